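#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// RFC-4180 tokenizer: quoted fields may contain the delimiter, doubled
// quotes, and embedded CR/LF.  With quoting disabled (TSV dialect) quotes
// are ordinary characters.  Rows are split on LF or CRLF outside quotes.
// A trailing newline does not create an empty final record.

// [[Rcpp::export(name = ".tokenize_delimited")]]
List tokenize_delimited(std::string content, char delim, bool quoting) {
  std::vector<std::vector<std::string>> rows;
  std::vector<std::string> row;
  std::string cell;
  bool in_quotes = false, cell_open = false;
  size_t n = content.size();
  for (size_t i = 0; i < n; ++i) {
    char c = content[i];
    if (in_quotes) {
      if (c == '"') {
        if (i + 1 < n && content[i + 1] == '"') { cell += '"'; ++i; }
        else in_quotes = false;
      } else cell += c;
      continue;
    }
    if (quoting && c == '"' && cell.empty() && !cell_open) {
      in_quotes = true; cell_open = true;
    } else if (c == delim) {
      row.push_back(cell); cell.clear(); cell_open = false;
    } else if (c == '\n' || c == '\r') {
      if (c == '\r' && i + 1 < n && content[i + 1] == '\n') ++i;
      row.push_back(cell); cell.clear(); cell_open = false;
      rows.push_back(row); row.clear();
    } else {
      cell += c; cell_open = true;
    }
  }
  if (in_quotes) stop("unterminated quoted field at end of input");
  if (cell_open || !cell.empty() || !row.empty()) {
    row.push_back(cell);
    rows.push_back(row);
  }
  List out(rows.size());
  for (size_t r = 0; r < rows.size(); ++r) {
    CharacterVector rv(rows[r].size());
    for (size_t j = 0; j < rows[r].size(); ++j)
      rv[j] = String(rows[r][j], CE_UTF8);
    out[r] = rv;
  }
  return out;
}
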