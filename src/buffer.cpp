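// Single-precision training buffer. Large epoch datasets are stored as
// float32 (inputs are normalized to ~[-1, 1], where single precision is
// ample for network inputs), halving resident memory versus an R array.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
SEXP cpp_alloc_f32(double n_elem) {
  XPtr<std::vector<float>> p(new std::vector<float>(
      static_cast<size_t>(n_elem), 0.0f), true);
  return p;
}

// [[Rcpp::export]]
void cpp_fill_f32(SEXP buf, double offset, const NumericVector &values) {
  XPtr<std::vector<float>> p(buf);
  const size_t off = static_cast<size_t>(offset);
  if (off + values.size() > p->size()) stop("buffer overflow");
  for (R_xlen_t i = 0; i < values.size(); ++i)
    (*p)[off + i] = static_cast<float>(values[i]);
}

// [[Rcpp::export]]
double cpp_f32_length(SEXP buf) {
  XPtr<std::vector<float>> p(buf);
  return static_cast<double>(p->size());
}
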