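#' Circadian sampling design of the expression experiment
#'
#' The six unevenly spaced circadian sampling times used throughout:
#' 30 min before and after lights-off (CT 11.5, 12.5), 30 min before the
#' middle of the night (CT 17.5), 30 min before and after lights-on
#' (CT 23.5, 0.5) and 30 min before noon (CT 5.5).
#'
#' @return Numeric vector of CT hours.
#' @export
circadian_design_times <- function() c(0.5, 5.5, 11.5, 12.5, 17.5, 23.5)

#' Expression matrix with circadian sample times
#'
#' Container for log-intensity values of genes x arrays together with the
#' circadian time and replicate of each array.
#'
#' @param values numeric matrix (genes x arrays) of log-intensities, with
#'   row names (gene ids); no missing values.
#' @param times CT hour of each array, in \[0, 24).
#' @param replicate replicate id per array (defaults to 1).
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, times, replicate = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene_", seq_len(nrow(values)))
  if (anyNA(values)) stop("missing values are not allowed; impute or drop first")
  stopifnot(length(times) == ncol(values), all(times >= 0 & times < 24))
  if (is.null(replicate)) replicate <- rep(1L, ncol(values))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("array_", seq_len(ncol(values)))
  structure(list(values = values, times = as.numeric(times),
                 replicate = replicate),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " arrays; times: ", paste(unique(x$times), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.expression_matrix <- function(x, ...) {
  df <- tibble::as_tibble(x$values, rownames = "gene")
  out <- tidyr::pivot_longer(df, -"gene", names_to = "array",
                             values_to = "intensity")
  out$time <- x$times[match(out$array, colnames(x$values))]
  out$replicate <- x$replicate[match(out$array, colnames(x$values))]
  out
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Spectral power at a frequency of 1/day
#'
#' The oscillation-strength statistic: the power spectral density of a
#' mean-centered expression profile at frequency 1/24 h^-1, evaluated as
#' the direct discrete Fourier projection
#' `pd = |sum(x_k exp(-2 pi i t_k / 24))|^2 / n`. Sampling times need not
#' be evenly spaced; replicates enter as separate samples at their own
#' times.
#'
#' @param values numeric intensities, one per array.
#' @param times CT hours matching `values`.
#' @return The power (intensity^2 units); shift-invariant, 0 for constant
#'   profiles.
#' @export
#' @examples
#' t6 <- rep(circadian_design_times(), 2)
#' pd_statistic(cos(2 * pi * t6 / 24), t6)
pd_statistic <- function(values, times) {
  stopifnot(length(values) == length(times), length(values) >= 4)
  if (length(unique(times)) < 2) stop("degenerate design: all times equal")
  x <- values - mean(values)
  z <- sum(x * exp(-2i * pi * times / 24))
  Mod(z)^2 / length(x)
}

#' Permutation p-value for diurnal oscillation
#'
#' Shuffles the intensities over the sampling times and recomputes the
#' 1/day spectral power; the p-value is `(1 + #{pd_perm >= pd_obs}) /
#' (n_perm + 1)`, the standard positively biased permutation estimate.
#'
#' @inheritParams pd_statistic
#' @param n_perm number of permutations (>= 1). The analysis default is
#'   1e5; tests use smaller values.
#' @param seed integer seed for the shuffles.
#' @return p-value in (0, 1\].
#' @export
permutation_p <- function(values, times, n_perm = 1e5, seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  obs <- pd_statistic(values, times)
  n <- length(values)
  w <- exp(-2i * pi * times / 24)
  x <- values - mean(values)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- matrix(0, n_perm, n)
  for (k in seq_len(n_perm)) perm[k, ] <- sample.int(n)
  pdp <- Mod(matrix(x[perm], n_perm, n) %*% w)^2 / n
  (1 + sum(pdp >= obs - 1e-12)) / (n_perm + 1)
}

#' Fourier phase of a diurnal profile
#'
#' The circadian time of the fitted cosine's peak. The harmonic at 1/24
#' h^-1 is fitted by least squares (`x ~ cos(w t) + sin(w t)`), which is
#' exact for a pure cosine under any sampling design — the raw Fourier
#' projection is biased by the unevenly spaced circadian design.
#'
#' @inheritParams pd_statistic
#' @return Phase in CT hours, in \[0, 24).
#' @export
estimate_phase <- function(values, times) {
  x <- values - mean(values)
  if (pd_statistic(values, times) < 1e-12)
    stop("phase undefined: no power at 1/day")
  w <- 2 * pi / 24
  X <- cbind(cos(w * times), sin(w * times))
  ab <- qr.coef(qr(cbind(1, X)), values)[2:3]
  # x ~ A cos(w (t - phase)): A cos(w phase) = a, A sin(w phase) = b
  ph <- (atan2(ab[2], ab[1]) / w) %% 24
  if (ph >= 24) ph <- ph - 24 # guard against floating-point 24.0
  ph
}

#' Per-gene rhythm statistics
#'
#' Computes the 1/day spectral power, permutation p-value and Fourier phase
#' for every gene of an expression matrix.
#'
#' @param em an [expression_matrix()].
#' @param n_perm permutations per gene.
#' @param seed base seed; gene g is shuffled with `seed + g` so results do
#'   not depend on evaluation order.
#' @return Tibble with columns `gene`, `pd`, `p_value`, `phase` (`NA` where
#'   the power is numerically zero).
#' @export
rhythm_statistics <- function(em, n_perm = 999, seed = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(unique(em$times)) < 4)
    stop("at least 4 distinct sampling times are required")
  genes <- rownames(em$values)
  purrr::map_dfr(seq_along(genes), function(g) {
    x <- em$values[g, ]
    tibble::tibble(
      gene = genes[g],
      pd = pd_statistic(x, em$times),
      p_value = permutation_p(x, em$times, n_perm, seed + g),
      phase = tryCatch(estimate_phase(x, em$times),
                       error = function(e) NA_real_))
  })
}

#' Select the least-oscillating set (LOS)
#'
#' The reference gene set used to anchor normalization: genes whose
#' permutation p-value on the raw (pre-normalization) matrix exceeds the
#' threshold, i.e. the genes with the least evidence of diurnal
#' oscillation. Alternatively the `k` genes with the largest p-values
#' (ties broken by smallest pd) can be requested, mirroring a fixed-size
#' reference set.
#'
#' @param stats per-gene tibble from [rhythm_statistics()] computed on the
#'   raw matrix.
#' @param p_threshold include genes with `p_value > p_threshold`.
#' @param k if given, ignore `p_threshold` and take the `k` least
#'   oscillating genes.
#' @return Character vector of gene ids.
#' @export
select_los <- function(stats, p_threshold = 0.5, k = NULL) {
  if (!is.null(k)) {
    ord <- order(-stats$p_value, stats$pd)
    return(stats$gene[ord[seq_len(min(k, nrow(stats)))]])
  }
  los <- stats$gene[stats$p_value > p_threshold]
  if (!length(los))
    stop("empty least-oscillating set; lower p_threshold ",
         "(normalization is undefined without reference genes)")
  los
}

#' LOS-anchored loess normalization
#'
#' For each array, fits a locally weighted linear regression (tricube
#' weights) of the deviation of that array's LOS-gene intensities from the
#' LOS genes' cross-array means, as a function of the mean intensity, and
#' subtracts the fitted correction from every gene on the array (evaluated
#' at the gene's intensity, clamped to the fitted range). Removes additive
#' array biases exactly and smooth intensity-dependent distortions
#' approximately.
#'
#' @param em an [expression_matrix()].
#' @param los gene ids of the least-oscillating set.
#' @param span loess span in (0, 1\] (default 0.75).
#' @return List with `normalized` (an `expression_matrix`) and `model`
#'   (per-array tibble of fitted correction curves: `array`, `at`,
#'   `correction`).
#' @export
loess_normalize <- function(em, los, span = 0.75) {
  stopifnot(inherits(em, "expression_matrix"), span > 0, span <= 1)
  los <- intersect(los, rownames(em$values))
  if (length(los) < 10)
    stop("LOS too small for local regression (", length(los), " genes)")
  ref <- rowMeans(em$values[los, , drop = FALSE])
  out <- em$values
  curves <- vector("list", ncol(out))
  for (a in seq_len(ncol(out))) {
    dev <- em$values[los, a] - ref
    fit <- loess(dev ~ ref, span = span, degree = 1,
                 family = "gaussian",
                 control = loess.control(surface = "direct"))
    at <- pmin(pmax(em$values[, a], min(ref)), max(ref))
    corr <- predict(fit, newdata = data.frame(ref = at))
    out[, a] <- em$values[, a] - corr
    grid <- seq(min(ref), max(ref), length.out = 50)
    curves[[a]] <- tibble::tibble(
      array = colnames(out)[a], at = grid,
      correction = predict(fit, newdata = data.frame(ref = grid)),
      span = span)
  }
  list(normalized = expression_matrix(out, em$times, em$replicate),
       model = dplyr::bind_rows(curves))
}

#' @importFrom stats loess.control
NULL

#' Full transcript-rhythm pipeline
#'
#' Raw-matrix rhythm statistics, LOS selection, loess normalization, and
#' recomputed statistics on the normalized matrix.
#'
#' @inheritParams rhythm_statistics
#' @inheritParams select_los
#' @inheritParams loess_normalize
#' @return A list of class `rhythm_result`: `stats` (per-gene tibble with
#'   `gene`, `pd`, `p_value`, `phase`, `in_los`, computed on the normalized
#'   matrix), `raw_stats`, `los`, `normalized`, `model`.
#' @export
rhythm_analysis <- function(em, n_perm = 999, seed = 1, p_threshold = 0.5,
                            k = NULL, span = 0.75) {
  raw <- rhythm_statistics(em, n_perm, seed)
  los <- select_los(raw, p_threshold, k)
  norm <- loess_normalize(em, los, span)
  stats <- rhythm_statistics(norm$normalized, n_perm, seed)
  stats$in_los <- stats$gene %in% los
  structure(list(stats = stats, raw_stats = raw, los = los,
                 normalized = norm$normalized, model = norm$model),
            class = "rhythm_result")
}

#' @export
print.rhythm_result <- function(x, ...) {
  cat("<rhythm_result> ", nrow(x$stats), " genes, ",
      length(x$los), " in the least-oscillating set\n", sep = "")
  invisible(x)
}

#' @export
tidy.rhythm_result <- function(x, ...) x$stats

#' @export
glance.rhythm_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$stats), n_los = length(x$los),
                 n_p05 = sum(x$stats$p_value <= 0.05))
}

#' Plot per-gene rhythm statistics
#'
#' Phase vs spectral power, colored by LOS membership.
#'
#' @param object a `rhythm_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rhythm_result <- function(object, ...) {
  df <- object$stats
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$pd,
                                   colour = .data$in_los)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "phase (CT h)", y = "power at 1/day",
                  colour = "in LOS") +
    ggplot2::theme_minimal()
}

#' Simulation configuration for diurnal expression data
#'
#' Generative model: gene g on array a (time t) has log-intensity
#' `baseline_g + A_g cos(2 pi (t - phase_g) / 24) * [g oscillating]
#'  + trend_a(t) + distortion_a(x) + noise`. The array trend is a global
#' additive shift increasing over the subjective day (higher expression
#' during the day), optionally plus a smooth intensity-dependent
#' distortion; both are what the LOS-anchored loess normalization is
#' designed to remove.
#'
#' @param n_genes number of genes.
#' @param fraction_oscillating fraction of genes given a cosine component.
#' @param amplitude_range uniform range of oscillation amplitudes.
#' @param noise_sd Gaussian noise standard deviation (log-intensity units).
#' @param baseline_mean,baseline_sd distribution of gene baselines.
#' @param trend_amplitude size of the additive day/night array trend.
#' @param distortion_amplitude amplitude of the smooth intensity-dependent
#'   distortion `a * sin(x)` (0 disables).
#' @param times sampling times (default the six circadian design times).
#' @param n_replicates arrays per time point.
#' @param seed RNG seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 1000,
                                  fraction_oscillating = 0.2,
                                  amplitude_range = c(0.5, 2),
                                  noise_sd = 0.3,
                                  baseline_mean = 10, baseline_sd = 1.5,
                                  trend_amplitude = 0,
                                  distortion_amplitude = 0,
                                  times = circadian_design_times(),
                                  n_replicates = 2,
                                  seed = 1) {
  stopifnot(fraction_oscillating >= 0, fraction_oscillating <= 1,
            noise_sd > 0, n_replicates >= 1)
  structure(as.list(environment()), class = "expression_sim_config")
}

#' Generate synthetic diurnal expression data
#'
#' Draws an expression matrix from the generative model of
#' [expression_sim_config()] together with its ground truth.
#'
#' @param config an [expression_sim_config()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (tibble: `gene`, `is_oscillating`, `amplitude`, `phase`).
#' @export
generate_expression <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_genes
  times <- rep(config$times, config$n_replicates)
  reps <- rep(seq_len(config$n_replicates), each = length(config$times))
  a <- length(times)
  osc <- seq_len(n) <= round(config$fraction_oscillating * n)
  amp <- ifelse(osc, runif(n, config$amplitude_range[1],
                           config$amplitude_range[2]), 0)
  phase <- ifelse(osc, runif(n, 0, 24), NA_real_)
  base <- rnorm(n, config$baseline_mean, config$baseline_sd)
  # additive array trend: higher over the subjective day, peak at noon
  trend <- config$trend_amplitude * cos(2 * pi * (times - 6) / 24)
  vals <- matrix(rnorm(n * a, 0, config$noise_sd), n, a)
  for (g in seq_len(n)) {
    sig <- base[g] + trend
    if (osc[g]) sig <- sig + amp[g] * cos(2 * pi * (times - phase[g]) / 24)
    vals[g, ] <- vals[g, ] + sig
  }
  if (config$distortion_amplitude > 0)
    vals <- vals + config$distortion_amplitude * sin(vals)
  rownames(vals) <- sprintf("gene_%04d", seq_len(n))
  colnames(vals) <- sprintf("array_t%04.1f_r%d", times, reps)
  list(matrix = expression_matrix(vals, times, reps),
       truth = tibble::tibble(gene = rownames(vals), is_oscillating = osc,
                              amplitude = amp, phase = phase))
}

#' Read an expression matrix from TSV files
#'
#' `expr_path`: first column gene id, remaining columns arrays.
#' `times_path`: columns `array`, `time` and optionally `replicate`.
#'
#' @param expr_path,times_path file paths.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(expr_path, times_path) {
  expr <- utils::read.delim(expr_path, check.names = FALSE)
  genes <- expr[[1]]
  vals <- as.matrix(expr[, -1, drop = FALSE])
  rownames(vals) <- genes
  design <- utils::read.delim(times_path)
  i <- match(colnames(vals), design$array)
  if (anyNA(i)) stop("array missing from design table: ",
                     colnames(vals)[which(is.na(i))[1]])
  expression_matrix(vals, design$time[i],
                    if ("replicate" %in% names(design)) design$replicate[i])
}

#' Write an expression matrix to TSV files
#'
#' @param em an [expression_matrix()].
#' @param expr_path,times_path output file paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression_tsv <- function(em, expr_path, times_path) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(array = colnames(em$values), time = em$times,
               replicate = em$replicate),
    times_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}
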