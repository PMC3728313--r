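# absolute-tolerance comparison (testthat's expect_equal tolerance is
# relative, which is the wrong scale for Monte-Carlo checks near zero)
expect_within <- function(actual, expected, tol, label = NULL) {
  if (is.null(label)) {
    label <- sprintf("%s (= %.4f) vs %.4f", deparse(substitute(actual)),
                     actual, expected)
  }
  expect_lt(abs(actual - expected), tol, label = label)
}
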