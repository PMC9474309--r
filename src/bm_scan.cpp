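#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Boyer-Moore scan with externally supplied shift tables.
//
// bad_char: last 0-based index of each of A,C,G,T in the pattern, -1 if
//   absent (any other text character, e.g. N, acts as -1 and never matches).
// good_suffix: length m+1; entry j (0-based vector index) is the shift after
//   a mismatch at 1-based pattern position j, entry 0 the shift after a full
//   match. All entries in [1, m].
// start_at: alignment offset where scanning begins (first offset whose final
//   characters align, from the first-occurrence heuristic); negative means
//   the pattern's final character never occurs, so the result is empty.
//
// Returns all 0-based occurrence starts, ascending.
// [[Rcpp::export(name = ".bm_scan_cpp")]]
IntegerVector bm_scan_cpp(std::string text, std::string pattern,
                          IntegerVector bad_char_acgt,
                          IntegerVector good_suffix, int start_at) {
  const long n = (long)text.size();
  const long m = (long)pattern.size();
  std::vector<int> hits;
  if (m == 0 || m > n || start_at < 0) return IntegerVector(0);
  if ((long)good_suffix.size() != m + 1)
    stop("good_suffix table must have length m + 1");

  int bc[256];
  for (int i = 0; i < 256; ++i) bc[i] = -1;
  bc[(unsigned char)'A'] = bad_char_acgt[0];
  bc[(unsigned char)'C'] = bad_char_acgt[1];
  bc[(unsigned char)'G'] = bad_char_acgt[2];
  bc[(unsigned char)'T'] = bad_char_acgt[3];

  long pos = start_at;
  while (pos <= n - m) {
    long j = m - 1;                       // 0-based pattern index, right to left
    while (j >= 0 && pattern[(size_t)j] == text[(size_t)(pos + j)]) --j;
    if (j < 0) {
      hits.push_back((int)pos);
      pos += good_suffix[0];              // full-match shift (pattern period)
    } else {
      long gs = good_suffix[j + 1];       // mismatch at 1-based position j+1
      long bcs = j - bc[(unsigned char)text[(size_t)(pos + j)]];
      pos += (gs > bcs) ? gs : bcs;
    }
  }
  return wrap(hits);
}

// Naive reference scan: checks every alignment character by character.
// Kept in C++ only for the generator's junction-cleanup loop on long
// sequences; the R-level naive oracle is independent of this file.
// [[Rcpp::export(name = ".naive_scan_cpp")]]
IntegerVector naive_scan_cpp(std::string text, std::string pattern) {
  const long n = (long)text.size();
  const long m = (long)pattern.size();
  std::vector<int> hits;
  for (long pos = 0; pos + m <= n; ++pos) {
    long j = 0;
    while (j < m && text[(size_t)(pos + j)] == pattern[(size_t)j]) ++j;
    if (j == m) hits.push_back((int)pos);
  }
  return wrap(hits);
}
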