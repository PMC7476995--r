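#' Specify paired differential-count simulations
#'
#' Emulates a method-comparison study: for each smear a true five-series
#' composition is drawn from a Dirichlet distribution, then two measurement
#' methods observe it with independent Gaussian noise.  Method B can carry a
#' proportional bias on one designated series (slope/intercept, with the
#' remaining series compensated so the pre-noise composition still sums to
#' 100) and/or a plain additive per-series shift.
#'
#' @param n_smears number of paired smears (>= 2).
#' @param true_series_concentration 5 positive Dirichlet weights in
#'   [series_names()] order; larger total = less between-smear spread.
#' @param method_a_noise_sd,method_b_noise_sd measurement noise, percentage
#'   points.
#' @param method_b_bias additive shift(s) for method B, percentage points;
#'   scalar or length-5 (recycled over series).
#' @param method_b_slope,method_b_intercept proportional bias applied to
#'   `bias_series` before noise: B = slope * true + intercept.
#' @param bias_series which series the proportional bias acts on.
#' @param seed integer seed.
#' @return object of class `paired_differential_spec`.
#' @export
paired_differential_spec <- function(n_smears = 124,
                                     true_series_concentration =
                                       c(granulocytes = 18, erythroid = 9,
                                         lymphoid = 6, monocytes = 1.5,
                                         plasma_cells = 1.5),
                                     method_a_noise_sd = 3,
                                     method_b_noise_sd = 3,
                                     method_b_bias = 0,
                                     method_b_slope = 1,
                                     method_b_intercept = 0,
                                     bias_series = "granulocytes",
                                     seed = 1) {
  stopifnot(n_smears >= 2,
            length(true_series_concentration) == 5,
            all(true_series_concentration > 0),
            method_a_noise_sd >= 0, method_b_noise_sd >= 0,
            length(method_b_bias) %in% c(1, 5),
            method_b_slope > 0, bias_series %in% series_names())
  structure(list(
    n_smears = as.integer(n_smears),
    true_series_concentration =
      stats::setNames(as.numeric(true_series_concentration), series_names()),
    method_a_noise_sd = method_a_noise_sd,
    method_b_noise_sd = method_b_noise_sd,
    method_b_bias = stats::setNames(rep(as.numeric(method_b_bias),
                                        length.out = 5), series_names()),
    method_b_slope = method_b_slope,
    method_b_intercept = method_b_intercept,
    bias_series = bias_series, seed = as.integer(seed)
  ), class = "paired_differential_spec")
}

#' Simulate paired five-series differential counts
#'
#' @param spec a [paired_differential_spec()].
#' @return long-format data.frame with columns `smear_id`, `series`,
#'   `method_a`, `method_b` (percentages, each method renormalized to sum to
#'   100 per smear).  Attributes: `truth` (n x 5 matrix of true percentages)
#'   and `raw` (list of pre-renormalization `method_a` / `method_b`
#'   matrices).
#' @export
simulate_paired_differentials <- function(spec) {
  stopifnot(inherits(spec, "paired_differential_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_smears
    conc <- spec$true_series_concentration
    # Dirichlet via normalized gamma draws
    g <- matrix(stats::rgamma(n * 5, shape = rep(conc, each = n)), nrow = n)
    truth <- 100 * g / rowSums(g)
    colnames(truth) <- series_names()

    a_raw <- truth +
      matrix(stats::rnorm(n * 5, 0, spec$method_a_noise_sd), nrow = n)

    b_true <- truth
    bs <- spec$bias_series
    if (spec$method_b_slope != 1 || spec$method_b_intercept != 0) {
      shifted <- spec$method_b_slope * truth[, bs] + spec$method_b_intercept
      rest <- setdiff(series_names(), bs)
      scale <- (100 - shifted) / pmax(100 - truth[, bs], 1e-9)
      b_true[, rest] <- truth[, rest] * scale
      b_true[, bs] <- shifted
    }
    b_raw <- b_true +
      matrix(spec$method_b_bias, nrow = n, ncol = 5, byrow = TRUE) +
      matrix(stats::rnorm(n * 5, 0, spec$method_b_noise_sd), nrow = n)
    colnames(a_raw) <- colnames(b_raw) <- series_names()

    renorm <- function(m) {
      m <- pmax(m, 0)
      100 * m / pmax(rowSums(m), 1e-9)
    }
    a <- renorm(a_raw); b <- renorm(b_raw)

    out <- data.frame(
      smear_id = rep(seq_len(n), times = 5),
      series = rep(series_names(), each = n),
      method_a = as.vector(a),
      method_b = as.vector(b),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$smear_id, match(out$series, series_names())), ]
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    attr(out, "raw") <- list(method_a = a_raw, method_b = b_raw)
    out
  })
}

#' Write / read paired differentials as CSV
#'
#' Column order is fixed: `smear_id,series,method_a,method_b`.
#'
#' @param x data.frame from [simulate_paired_differentials()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_paired_csv <- function(x, path) {
  utils::write.csv(x[, c("smear_id", "series", "method_a", "method_b")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_paired_csv
#' @export
read_paired_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("smear_id", "series", "method_a", "method_b")
  if (!all(need %in% names(df))) {
    stop("paired CSV must have columns ", paste(need, collapse = ","))
  }
  df[, need]
}
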