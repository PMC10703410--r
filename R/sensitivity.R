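## Variance-based (Sobol) global sensitivity analysis with the paired-matrix
## Monte-Carlo estimator of Azzini and co-workers and bootstrap percentile
## confidence intervals.

#' Build a paired-matrix Sobol design
#'
#' Generates two independent base matrices A and B (N rows each, uniform over
#' the input ranges) and, for every input i, the hybrid matrices AB_i (A with
#' column i from B) and BA_i (B with column i from A). Total rows:
#' 2N(1 + p).
#'
#' @param N base sample count (a power of 2 by convention, >= 2)
#' @param ranges named list of `c(min, max)` ranges, one per input
#' @param seed RNG seed for reproducibility
#' @return object of class `cr_sobol_design`: the row-bound design matrix
#'   (`$X`), block bookkeeping, and the generator settings
#' @export
#' @examples
#' d <- sobol_design(8, list(a = c(0, 1), b = c(0, 1)), seed = 1)
#' nrow(d$X) # 2 * 8 * (1 + 2)
sobol_design <- function(N, ranges, seed = 1) {
  if (!is.finite(N) || N < 2) stop("sobol_design: N must be >= 2")
  N <- as.integer(N)
  p <- length(ranges)
  if (p < 1 || is.null(names(ranges)) || any(!nzchar(names(ranges)))) {
    stop("sobol_design: ranges must be a named list")
  }
  set.seed(seed)
  U <- matrix(runif(2 * N * p), nrow = 2 * N, ncol = p)
  A <- U[seq_len(N), , drop = FALSE]
  B <- U[N + seq_len(N), , drop = FALSE]
  blocks <- vector("list", 2 + 2 * p)
  X01 <- rbind(A, B)
  labels <- c(rep("A", N), rep("B", N))
  for (i in seq_len(p)) {
    ABi <- A; ABi[, i] <- B[, i]
    BAi <- B; BAi[, i] <- A[, i]
    X01 <- rbind(X01, ABi, BAi)
    labels <- c(labels, rep(paste0("AB", i), N), rep(paste0("BA", i), N))
  }
  lo <- vapply(ranges, `[`, 0, 1); hi <- vapply(ranges, `[`, 0, 2)
  X <- sweep(sweep(X01, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(X) <- names(ranges)
  structure(list(X = X, labels = labels, N = N, p = p,
                 inputs = names(ranges), ranges = ranges, seed = seed),
            class = "cr_sobol_design")
}

#' @keywords internal
sobol_blocks <- function(design, y) {
  if (length(y) != nrow(design$X)) stop("outputs do not match the design")
  N <- design$N; p <- design$p
  yA <- y[design$labels == "A"]; yB <- y[design$labels == "B"]
  AB <- lapply(seq_len(p), function(i) y[design$labels == paste0("AB", i)])
  BA <- lapply(seq_len(p), function(i) y[design$labels == paste0("BA", i)])
  list(yA = yA, yB = yB, AB = AB, BA = BA, N = N, p = p)
}

#' @keywords internal
azzini_indices <- function(b, rows = seq_len(b$N)) {
  yA <- b$yA[rows]; yB <- b$yB[rows]
  S1 <- ST <- numeric(b$p)
  for (i in seq_len(b$p)) {
    yAB <- b$AB[[i]][rows]; yBA <- b$BA[[i]][rows]
    VT <- sum((yA - yB)^2 + (yBA - yAB)^2)
    if (VT <= 0) stop("undefined variance: all model outputs are constant")
    S1[i] <- 2 * sum((yBA - yB) * (yA - yAB)) / VT
    ST[i] <- sum((yB - yBA)^2 + (yA - yAB)^2) / VT
  }
  list(S1 = S1, ST = ST)
}

#' Sobol first- and total-order indices (Azzini estimator)
#'
#' @param design `cr_sobol_design`
#' @param y model outputs, one per design row (same order as `design$X`)
#' @return data.frame with columns `input`, `S1`, `ST`
#' @export
sobol_indices <- function(design, y) {
  if (any(!is.finite(y))) stop("sobol_indices: outputs must be finite")
  b <- sobol_blocks(design, y)
  est <- azzini_indices(b)
  data.frame(input = design$inputs, S1 = est$S1, ST = est$ST,
             row.names = NULL)
}

#' Bootstrap percentile intervals for Sobol indices
#'
#' Resamples the paired design rows with replacement and recomputes the
#' Azzini estimator.
#'
#' @param design `cr_sobol_design`
#' @param y model outputs
#' @param replicates bootstrap replicates (default 1000)
#' @param conf confidence level (default 0.95)
#' @param seed RNG seed
#' @return data.frame with `input`, `S1`, `S1_lo`, `S1_hi`, `ST`, `ST_lo`,
#'   `ST_hi`, and a `replicates` attribute
#' @export
sobol_bootstrap_ci <- function(design, y, replicates = 1000, conf = 0.95,
                               seed = 1) {
  b <- sobol_blocks(design, y)
  est <- azzini_indices(b)
  set.seed(seed)
  S1r <- matrix(NA_real_, replicates, b$p)
  STr <- matrix(NA_real_, replicates, b$p)
  for (r in seq_len(replicates)) {
    rows <- sample.int(b$N, b$N, replace = TRUE)
    er <- azzini_indices(b, rows)
    S1r[r, ] <- er$S1; STr[r, ] <- er$ST
  }
  a <- (1 - conf) / 2
  out <- data.frame(
    input = design$inputs,
    S1 = est$S1,
    S1_lo = apply(S1r, 2, quantile, probs = a),
    S1_hi = apply(S1r, 2, quantile, probs = 1 - a),
    ST = est$ST,
    ST_lo = apply(STr, 2, quantile, probs = a),
    ST_hi = apply(STr, 2, quantile, probs = 1 - a),
    row.names = NULL)
  attr(out, "replicates") <- replicates
  out
}

#' Mechanism inputs for the sensitivity study
#'
#' The eight inputs: seven single-parameter mechanisms plus the composite
#' hypertension severity, each as a severity fraction over its simulated
#' range.
#'
#' @return named list of `c(0, 1)` severity ranges
#' @export
sobol_mechanism_ranges <- function() {
  mechs <- c("lv_stiffness", "contractility", "outward_dilatation",
             "slowed_relaxation", "arterial_compliance", "venous_compliance",
             "venous_capacitance", "hypertension")
  setNames(rep(list(c(0, 1)), length(mechs)), mechs)
}

#' Evaluate LVEDP and EF at one severity combination
#'
#' Applies every mechanism at its severity and runs a settling simulation
#' with remodeling off.
#'
#' @param severities named numeric vector over [sobol_mechanism_ranges()] names
#' @param base healthy `cr_params` (with setpoints, for speed)
#' @param days settling duration; the reduced-cost surrogate mode uses a
#'   shorter settle than the faithful 60 days
#' @return c(LVEDP, EF)
#' @export
sobol_model_eval <- function(severities, base, days = 60) {
  specs <- lapply(names(severities), function(m)
    mechanism_spec(m, unname(severities[[m]])))
  p <- apply_mechanisms(base, specs)
  p$remodel$K_l <- 0; p$remodel$K_d <- 0
  sim <- run_simulation(p, days = days)
  c(LVEDP = sim$final$LVEDP, EF = sim$final$EF)
}

#' Run the full mechanism sensitivity study
#'
#' Builds the paired-matrix design over the eight mechanism severities,
#' evaluates the settled LVEDP and EF for every row, and returns Azzini
#' indices with bootstrap confidence intervals for both outputs.
#'
#' @param N base sample count (the full-scale study uses 2^9; reduced N with
#'   a shorter settle gives a desk-scale approximation)
#' @param seed RNG seed
#' @param days settling duration per evaluation
#' @param base optional healthy `cr_params`
#' @param replicates bootstrap replicates
#' @param progress print progress every 100 evaluations
#' @param surrogate reduced-cost mode: coarser beat step and looser
#'   macro-step control (a few-percent approximation of the settled state;
#'   not the full-fidelity configuration)
#' @return list: `design`, `outputs` (matrix), `LVEDP` and `EF` index tables
#' @export
sobol_study <- function(N = 2^5, seed = 1, days = 60, base = NULL,
                        replicates = 1000, progress = FALSE,
                        surrogate = FALSE) {
  if (is.null(base)) base <- default_parameters()
  if (is.null(base$setpoints)) base <- compute_setpoints(base)
  if (surrogate) {
    base$solver$beat_dt <- 5e-4
    base$solver$beat_tol <- 0.02
    base$solver$slow_rel_change <- 0.03
    base$solver$slow_dt_max <- 0.2
  }
  design <- sobol_design(N, sobol_mechanism_ranges(), seed = seed)
  n <- nrow(design$X)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("LVEDP", "EF")))
  for (r in seq_len(n)) {
    out[r, ] <- tryCatch(sobol_model_eval(design$X[r, ], base, days = days),
                         error = function(e) c(NA_real_, NA_real_))
    if (progress && r %% 100 == 0) message("sobol: ", r, "/", n)
  }
  # failed evaluations are excluded pairwise with their design partners
  bad <- !is.finite(out[, 1]) | !is.finite(out[, 2])
  if (mean(bad) > 0.01) stop("more than 1% of sensitivity rows failed")
  if (any(bad)) {
    v <- ((seq_len(n) - 1) %% design$N) + 1
    drop_v <- unique(v[bad])
    keep <- !(v %in% drop_v)
    design$X <- design$X[keep, , drop = FALSE]
    design$labels <- design$labels[keep]
    design$N <- design$N - length(drop_v)
    out <- out[keep, , drop = FALSE]
    message("sobol: excluded ", length(drop_v), " design pairs after failures")
  }
  list(design = design, outputs = out,
       LVEDP = sobol_bootstrap_ci(design, out[, "LVEDP"],
                                  replicates = replicates, seed = seed),
       EF = sobol_bootstrap_ci(design, out[, "EF"],
                               replicates = replicates, seed = seed))
}
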