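# Small in-code fixtures shared across test files.

make_ft <- function(values, kind = "species", scale = "relative",
                    features = NULL, samples = NULL) {
  if (is.null(features)) features <- sprintf("F%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  feature_table(values, kind = kind, scale = scale)
}

make_meta <- function(groups = c("CON", "RMT", "RFT"),
                      days = c(15, 35, 56), n_calves = 2,
                      total_reads = 1e5) {
  rows <- expand.grid(calf = seq_len(n_calves), day = days, group = groups,
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s%02d_d%d", rows$group, rows$calf, rows$day),
    calf_id = sprintf("%s%02d", rows$group, rows$calf),
    group = rows$group, day = rows$day, total_reads = total_reads,
    stringsAsFactors = FALSE)
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# Pearson correlation of a bivariate normal sample, the effect-size
# generator used by the meta-analysis calibration checks.
bivariate_r <- function(rho, n) {
  x <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, rho, rho, 1), 2))
  stats::cor(x)[1, 2]
}
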