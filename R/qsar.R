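#' Fingerprint bit order
#'
#' FP1 salt bridge Asp351; FP2 H-bond Glu353; FP3 H-bond His524; FP4
#' H-bond Thr347; FP5 internal hydrogen-bond count; FP6 hydrophobic
#' contact log P_C. Frozen in this order in every serialization.
#'
#' @return character vector of bit names.
#' @export
fingerprint_bits <- function() {
  c("FP1", "FP2", "FP3", "FP4", "FP5", "FP6")
}

.bit_feature_map <- c(
  FP1 = "salt_bridge_D351", FP2 = "hb_E353", FP3 = "hb_H524",
  FP4 = "hb_T347"
)

#' Published QSAR model
#'
#' The six-feature linear model log RBA = sum(c_i FP_i) + C with the
#' published coefficients: FP1 0.923, FP2 2.209, FP3 1.689, FP4 1.487,
#' FP5 0.614, FP6 3.861, intercept -9.341. The intercept is the affinity
#' of a ligand making no scored interaction (about 1e-9 RBA).
#'
#' @return object of class `qsar_model`.
#' @export
published_model <- function() {
  qsar_model(
    coefficients = c(FP1 = 0.923, FP2 = 2.209, FP3 = 1.689,
                     FP4 = 1.487, FP5 = 0.614, FP6 = 3.861),
    intercept = -9.341,
    diagnostics = list(source = "published")
  )
}

#' QSAR model constructor
#'
#' @param coefficients named numeric vector of per-bit coefficients.
#' @param intercept numeric scalar.
#' @param diagnostics optional list (R2, Q2, n, ...).
#' @return object of class `qsar_model`.
#' @export
qsar_model <- function(coefficients, intercept, diagnostics = list()) {
  stopifnot(!is.null(names(coefficients)), is.numeric(intercept))
  structure(
    list(coefficients = coefficients, intercept = intercept,
         feature_mask = names(coefficients), diagnostics = diagnostics),
    class = "qsar_model"
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("<qsar_model> logRBA = ")
  cat(paste(sprintf("%.3f*%s", x$coefficients, names(x$coefficients)),
            collapse = " + "))
  cat(sprintf(" + (%.3f)\n", x$intercept))
  if (!is.null(x$diagnostics$R2)) {
    cat(sprintf("  R2 = %.3f", x$diagnostics$R2))
    if (!is.null(x$diagnostics$Q2)) cat(sprintf(", Q2 = %.3f",
                                                x$diagnostics$Q2))
    cat(sprintf(", n = %d\n", x$diagnostics$n))
  }
  invisible(x)
}

#' Assemble the interaction fingerprint
#'
#' Maps detected feature hits and the hydrophobic contact integral onto
#' the FP1-FP6 vector. Extra candidate features (Leu346 hydrogen bond,
#' Arg394 acceptance, Phe404 T-stack) are carried as `candidate_bits`;
#' the full hit list is retained as provenance.
#'
#' @param hits list of `feature_hit` (see [detect_features()]).
#' @param logpc hydrophobic contact value (FP6), non-negative.
#' @param cplx optional `complex_structure` recorded for provenance.
#' @return object of class `interaction_fingerprint`.
#' @export
build_fingerprint <- function(hits, logpc, cplx = NULL) {
  stopifnot(logpc >= 0)
  feats <- vapply(hits, function(h) h$feature, character(1))
  fp <- stats::setNames(numeric(6), fingerprint_bits())
  for (bit in names(.bit_feature_map)) {
    fp[bit] <- as.numeric(.bit_feature_map[bit] %in% feats)
  }
  n_int <- 0L
  k <- match("internal_hb", feats)
  if (!is.na(k)) n_int <- as.integer(hits[[k]]$measured["count"])
  fp["FP5"] <- n_int
  fp["FP6"] <- logpc
  structure(
    list(
      fp = fp,
      candidate_bits = c(
        hb_L346 = as.numeric("hb_L346" %in% feats),
        hb_R394 = as.numeric("hb_R394" %in% feats),
        pistack_F404 = as.numeric("pistack_F404" %in% feats)
      ),
      provenance = hits,
      complex = if (is.null(cplx)) NULL else cplx$receptor_label
    ),
    class = "interaction_fingerprint"
  )
}

#' @export
print.interaction_fingerprint <- function(x, ...) {
  cat("<interaction_fingerprint> ",
      paste(sprintf("%s=%.3g", names(x$fp), x$fp), collapse = " "), "\n")
  invisible(x)
}

#' Predict log RBA from a fingerprint
#'
#' log RBA = C + sum c_i FP_i, with the per-feature contribution breakdown
#' retained (the breakdown plus intercept reproduces the prediction
#' exactly).
#'
#' @param fp an `interaction_fingerprint` or a named numeric vector.
#' @param model a `qsar_model`.
#' @return object of class `rba_prediction` with `log_rba` and
#'   `per_feature_contribution`.
#' @export
predict_log_rba <- function(fp, model = published_model()) {
  v <- if (inherits(fp, "interaction_fingerprint")) {
    c(fp$fp, fp$candidate_bits)
  } else fp
  missing <- setdiff(names(model$coefficients), names(v))
  if (length(missing)) {
    stop("fingerprint lacks bits required by the model: ",
         paste(missing, collapse = ", "))
  }
  contrib <- model$coefficients * v[names(model$coefficients)]
  structure(
    list(log_rba = unname(model$intercept + sum(contrib)),
         per_feature_contribution = contrib,
         intercept = model$intercept),
    class = "rba_prediction"
  )
}

#' @export
print.rba_prediction <- function(x, ...) {
  cat(sprintf("<rba_prediction> logRBA = %.3f (RBA %.3g%%)\n",
              x$log_rba, 10^x$log_rba))
  invisible(x)
}

#' Ordinary least-squares fit of the fingerprint model
#'
#' @param X numeric matrix or data.frame of fingerprint bits (columns
#'   named).
#' @param y numeric vector of log RBA values.
#' @param mask column names (or indices) to include; default all.
#' @return a `qsar_model` with training R2 in `diagnostics`.
#' @export
fit_mlr <- function(X, y, mask = colnames(X)) {
  X <- as.matrix(X)
  if (is.numeric(mask)) mask <- colnames(X)[mask]
  stopifnot(all(mask %in% colnames(X)))
  Xm <- X[, mask, drop = FALSE]
  n <- nrow(Xm)
  if (n <= length(mask) + 1) {
    stop("need more observations (", n, ") than features + 1 (",
         length(mask) + 1, ")")
  }
  D <- cbind(`(Intercept)` = 1, Xm)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("rank-deficient design; collinear bits: ",
         paste(drop_cols, collapse = ", "))
  }
  fit <- stats::lm.fit(D, y)
  co <- fit$coefficients
  yhat <- D %*% co
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  qsar_model(
    coefficients = co[mask],
    intercept = unname(co["(Intercept)"]),
    diagnostics = list(R2 = unname(r2), n = n, residuals = y - drop(yhat))
  )
}

#' Leave-one-out cross-validated Q2
#'
#' Q2 = 1 - PRESS/TSS with each observation predicted from the model fit
#' to the remaining n - 1. Computed through the exact OLS identity
#' e_(i) = e_i / (1 - h_ii); identical to refitting n models.
#'
#' @inheritParams fit_mlr
#' @return numeric Q2 (at most 1; can be negative).
#' @export
loo_q2 <- function(X, y, mask = colnames(X)) {
  X <- as.matrix(X)
  if (is.numeric(mask)) mask <- colnames(X)[mask]
  Xm <- X[, mask, drop = FALSE]
  n <- nrow(Xm)
  if (n < length(mask) + 2) {
    stop("need n >= |mask| + 2 for leave-one-out validation")
  }
  D <- cbind(1, Xm)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    stop("rank-deficient design; collinear bits in mask: ",
         paste(mask, collapse = ", "))
  }
  fit <- stats::lm.fit(D, y)
  e <- y - D %*% fit$coefficients
  h <- rowSums(qr.Q(qrD)[, seq_len(qrD$rank), drop = FALSE]^2)
  press <- sum((e / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

.mask_key <- function(mask) paste(sort(mask), collapse = "|")

.safe_q2 <- function(X, y, mask) {
  tryCatch(loo_q2(X, y, mask), error = function(e) -Inf)
}

#' Exhaustive feature-subset search
#'
#' Evaluates every non-empty subset of the candidate bits by leave-one-out
#' Q2; ties broken toward fewer features, then lexicographically. Used as
#' the reference for the genetic-algorithm search.
#'
#' @inheritParams fit_mlr
#' @return list with `mask` and fitted `model`.
#' @export
exhaustive_select <- function(X, y) {
  X <- as.matrix(X)
  bits <- colnames(X)
  best <- NULL
  for (sz in seq_along(bits)) {
    for (comb in utils::combn(bits, sz, simplify = FALSE)) {
      q2 <- .safe_q2(X, y, comb)
      if (is.null(best) || q2 > best$q2 + 1e-12 ||
          (abs(q2 - best$q2) <= 1e-12 && sz < length(best$mask))) {
        best <- list(mask = comb, q2 = q2)
      }
    }
  }
  model <- fit_mlr(X, y, best$mask)
  model$diagnostics$Q2 <- best$q2
  list(mask = best$mask, model = model)
}

#' GA settings
#'
#' @param population_size number of masks per generation (>= 2).
#' @param generations number of generations (0 returns the best of the
#'   random initial population).
#' @param crossover_rate probability of uniform crossover per mating.
#' @param mutation_rate per-bit flip probability.
#' @param elitism number of top masks copied unchanged.
#' @param seed integer seed making the search deterministic.
#' @return list of settings.
#' @export
ga_config <- function(population_size = 50, generations = 100,
                      crossover_rate = 0.9, mutation_rate = 1 / 9,
                      elitism = 1, seed = 1) {
  if (population_size < 2) stop("population_size must be at least 2")
  list(population_size = population_size, generations = generations,
       crossover_rate = crossover_rate, mutation_rate = mutation_rate,
       elitism = elitism, seed = seed)
}

#' Genetic-algorithm feature selection (GA-MLR)
#'
#' Binary-mask GA over the candidate fingerprint bits. Fitness is the
#' leave-one-out Q2 of the OLS fit on the masked bits (invalid masks score
#' -Inf); ties favor fewer features. Tournament selection, uniform
#' crossover, per-bit mutation, elitism; fully deterministic given the
#' seed. The returned model is refit on all data with the winning mask.
#'
#' @inheritParams fit_mlr
#' @param config settings from [ga_config()].
#' @return list with `mask`, fitted `model`, and the fitness `history`.
#' @export
ga_select <- function(X, y, config = ga_config()) {
  X <- as.matrix(X)
  bits <- colnames(X)
  nb <- length(bits)
  cache <- new.env(parent = emptyenv())
  fitness <- function(mask_vec) {
    if (!any(mask_vec)) return(-Inf)
    key <- paste(as.integer(mask_vec), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    q2 <- .safe_q2(X, y, bits[mask_vec])
    # parsimony tie-break folded into fitness at below-tolerance scale
    val <- q2 - 1e-9 * sum(mask_vec)
    cache[[key]] <- val
    val
  }
  run <- function() {
    pop <- matrix(stats::runif(config$population_size * nb) < 0.5,
                  nrow = config$population_size)
    # guarantee no empty mask in the initial population
    for (i in seq_len(nrow(pop))) {
      if (!any(pop[i, ])) pop[i, sample.int(nb, 1)] <- TRUE
    }
    fit <- apply(pop, 1, fitness)
    if (config$generations > 0) {
      for (g in seq_len(config$generations)) {
        ord <- order(fit, decreasing = TRUE)
        newpop <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
        while (nrow(newpop) < config$population_size) {
          pick <- function() {
            cand <- sample.int(config$population_size, 2)
            cand[which.max(fit[cand])]
          }
          p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
          if (stats::runif(1) < config$crossover_rate) {
            sw <- stats::runif(nb) < 0.5
            child <- ifelse(sw, p1, p2)
          } else child <- p1
          flip <- stats::runif(nb) < config$mutation_rate
          child <- xor(child, flip)
          if (!any(child)) child[sample.int(nb, 1)] <- TRUE
          newpop <- rbind(newpop, child)
        }
        pop <- newpop
        fit <- apply(pop, 1, fitness)
      }
    }
    best <- which.max(fit)
    list(mask_vec = pop[best, ], fit = fit[best])
  }
  res <- with_seed(config$seed, run())
  mask <- bits[res$mask_vec]
  model <- fit_mlr(X, y, mask)
  model$diagnostics$Q2 <- loo_q2(X, y, mask)
  list(mask = mask, model = model, history = res$fit)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write fingerprint tables
#'
#' Delimited text with header FP1..FP6 + logRBA. Integer bits are written
#' bit-exact; FP6 with three decimals.
#'
#' @param path file path.
#' @return `read_fingerprint_table`: data.frame; `write_fingerprint_table`:
#'   `path`, invisibly.
#' @export
read_fingerprint_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c(fingerprint_bits(), "logRBA")
  if (!all(need %in% names(df))) {
    stop("fingerprint table must have columns: ",
         paste(need, collapse = ", "))
  }
  df
}

#' @param df data.frame with FP1..FP6 and logRBA columns.
#' @rdname read_fingerprint_table
#' @export
write_fingerprint_table <- function(df, path) {
  out <- df
  for (b in c("FP1", "FP2", "FP3", "FP4", "FP5")) {
    out[[b]] <- as.integer(round(out[[b]]))
  }
  out$FP6 <- sprintf("%.3f", out$FP6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
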