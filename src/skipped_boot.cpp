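// Strict bootstrap for the skipped correlation: each draw resamples the full
// data, re-runs the projection outlier rule (componentwise-median center,
// MAD-normalized distances, chi-square cutoff), and computes Pearson's r on
// the retained pairs. Resampling indices are drawn in R so that results are
// reproducible under R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double MAD_CONST = 1.4826;

// [[Rcpp::export(name = ".skippedBootStrict")]]
arma::vec skipped_boot_strict(const arma::vec& x, const arma::vec& y,
                              const arma::umat& idx, double cutoff) {
  const uword n = x.n_elem;
  const uword B = idx.n_cols;
  vec out(B);
  out.fill(datum::nan);

  for (uword b = 0; b < B; ++b) {
    vec xb(n), yb(n);
    for (uword i = 0; i < n; ++i) {
      uword j = idx(i, b) - 1;  // 1-based from R
      xb(i) = x(j);
      yb(i) = y(j);
    }
    double cx = median(xb), cy = median(yb);
    mat centered(n, 2);
    centered.col(0) = xb - cx;
    centered.col(1) = yb - cy;

    // projections onto directions through the center and each point; the
    // projection median and MAD are computed on the distinct values, since
    // the resampled duplicates would otherwise shrink the scale estimate and
    // inflate the flagging rate far beyond that of the original sample
    uvec flagged(n, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      double dx = centered(i, 0), dy = centered(i, 1);
      double nd = std::sqrt(dx * dx + dy * dy);
      if (nd == 0) continue;
      vec proj = (centered.col(0) * (dx / nd)) + (centered.col(1) * (dy / nd));
      vec uproj = unique(proj);  // sorted distinct values
      double med = median(uproj);
      double s = MAD_CONST * median(abs(uproj - med));
      if (s == 0) continue;
      for (uword k = 0; k < n; ++k)
        if (std::abs(proj(k) - med) / s > cutoff) flagged(k) = 1;
    }

    // Pearson on retained pairs
    uvec keep = find(flagged == 0);
    if (keep.n_elem < 4) continue;
    vec xk = xb(keep), yk = yb(keep);
    double sx = stddev(xk), sy = stddev(yk);
    if (sx == 0 || sy == 0) continue;
    out(b) = as_scalar(cor(xk, yk));
  }
  return out;
}
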