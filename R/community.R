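## Community-level statistics: Shannon alpha diversity, Bray-Curtis beta
## diversity, classical PCoA, the exact two-tailed Mann-Whitney test used
## for all control-vs-condition contrasts, and fivefold modulation
## classification.

check_composition <- function(a, what) {
  if (!is.numeric(a) || anyNA(a)) stop_input("%s must be numeric without NA", what)
  if (any(a < 0)) stop_input("%s has negative entries", what)
  if (abs(sum(a) - 1) > 1e-6) stop_input("%s must sum to 1", what)
  invisible(a)
}

#' Shannon alpha diversity
#'
#' `H = -sum(a_i log a_i)` over non-zero relative abundances, in natural-log
#' units (nats).
#'
#' @param abundances relative abundances of one sample (summing to 1).
#' @return Non-negative diversity value; 0 for a single-taxon community,
#'   `log(k)` for a uniform community of k taxa.
#' @export
shannon_diversity <- function(abundances) {
  check_composition(abundances, "`abundances`")
  a <- abundances[abundances > 0]
  -sum(a * log(a))
}

#' Bray-Curtis dissimilarity of two closed compositions
#'
#' `d = 1 - sum(min(a_i, b_i))` for relative abundances over a shared taxon
#' index: 0 for identical samples, 1 for disjoint supports.
#'
#' @param sample_a,sample_b relative abundance vectors over the same taxa
#'   (names, when present, must match).
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(sample_a, sample_b) {
  if (length(sample_a) != length(sample_b)) {
    stop_input("samples must share one taxon index")
  }
  if (!is.null(names(sample_a)) && !is.null(names(sample_b)) &&
      !identical(names(sample_a), names(sample_b))) {
    stop_input("sample taxon names do not match")
  }
  check_composition(sample_a, "`sample_a`")
  check_composition(sample_b, "`sample_b`")
  1 - sum(pmin(sample_a, sample_b))
}

#' Bray-Curtis dissimilarity matrix of an abundance table
#'
#' @param table a relative-mode `abund_table` (counts are converted).
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(table) {
  rel <- to_relative(table)
  n <- ncol(rel$mat)
  d <- matrix(0, n, n, dimnames = list(colnames(rel$mat), colnames(rel$mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d[i, j] <- d[j, i] <- bray_curtis(rel$mat[, i], rel$mat[, j])
    }
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared dissimilarity matrix and eigen-decomposes it.
#' Coordinates are returned for positive eigenvalues; negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported, not silently dropped.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (or a
#'   `dist`).
#' @return Object of class `scfa_pcoa`: list with `coords` (samples x
#'   axes), `eig` (all eigenvalues) and `explained` (fractions of the
#'   positive eigenvalue sum).
#' @export
pcoa <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_input("`d` must be square")
  if (any(abs(d - t(d)) > 1e-8)) stop_input("`d` must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_input("`d` must have a zero diagonal")
  n <- nrow(d)
  if (n < 2) stop_input("need at least two samples")
  ## cmdscale warns when trailing eigenvalues are <= 0; we report them all
  fit <- suppressWarnings(cmdscale(as.dist(d), k = n - 1L, eig = TRUE))
  coords <- fit$points
  if (!is.null(coords) && ncol(coords) > 0) {
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  }
  pos <- fit$eig[fit$eig > 0]
  explained <- if (length(pos) > 0) fit$eig / sum(pos) else rep(0, length(fit$eig))
  structure(list(coords = coords, eig = fit$eig, explained = explained),
            class = "scfa_pcoa")
}

#' @export
print.scfa_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive eigenvalue axes (%d negative eigenvalues)\n",
              nrow(x$coords), sum(x$eig > 0), sum(x$eig < 0)))
  if (sum(x$eig > 0) >= 2) {
    cat(sprintf("First two axes explain %.1f%% + %.1f%% of positive inertia\n",
                100 * x$explained[1], 100 * x$explained[2]))
  }
  invisible(x)
}

#' @export
plot.scfa_pcoa <- function(x, groups = NULL, ...) {
  if (is.null(x$coords) || ncol(x$coords) < 2) {
    stop_input("fewer than two positive axes; nothing to plot")
  }
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  plot(x$coords[, 1], x$coords[, 2], col = col, pch = 19,
       xlab = sprintf("PCo1 (%.1f%%)", 100 * x$explained[1]),
       ylab = sprintf("PCo2 (%.1f%%)", 100 * x$explained[2]), ...)
  if (!is.null(groups)) {
    legend("topright", legend = levels(factor(groups)), col =
             seq_along(levels(factor(groups))), pch = 19, cex = 0.7)
  }
  invisible(x)
}

#' Exact two-tailed Mann-Whitney test
#'
#' Computes the Mann-Whitney U of the first group from rank sums (mid-ranks
#' for ties). For `n_a + n_b <= exact_limit` the p value is exact: the
#' permutation null over all group labelings is fully enumerated and the
#' smaller one-sided tail probability of a U at least as extreme is
#' doubled, capped at 1 (the doubled-tail convention). Larger groups use a
#' tie-corrected normal approximation with continuity correction.
#'
#' Two completely separated groups of 4 attain the minimal two-tailed
#' p = 2/70 ~ 0.0286, i.e. P = 0.03 at two decimals.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param exact_limit largest `n_a + n_b` for exact enumeration
#'   (default 12).
#' @return `htest`-like list with `statistic` (U of group_a), `p.value`,
#'   and `exact` flag.
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))$p.value  # 2/70
mann_whitney_exact <- function(group_a, group_b, exact_limit = 12L) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_input("each group needs at least two values")
  }
  if (anyNA(group_a) || anyNA(group_b)) stop_input("groups must not contain NA")
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))          # mid-ranks for ties
  ## work on doubled rank sums so tied mid-ranks stay integral
  r2 <- as.integer(round(2 * r))
  u2_obs <- sum(r2[seq_len(na)]) - na * (na + 1L)
  exact <- n <= exact_limit

  if (exact) {
    labelings <- combn(n, na)
    u2_null <- colSums(matrix(r2[labelings], nrow = na)) - na * (na + 1L)
    p_low <- mean(u2_null <= u2_obs)
    p_high <- mean(u2_null >= u2_obs)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    u <- u2_obs / 2
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  structure(list(statistic = c(U = u2_obs / 2), p.value = p,
                 exact = exact,
                 method = "Exact two-tailed Mann-Whitney (doubled tail)",
                 data.name = "group_a vs group_b"),
            class = "htest")
}

#' Classify fold modulation of a taxon or phenotype
#'
#' Compares mean abundances between treatment and control: ratios strictly
#' above the fold threshold (default 5) in either direction are classed
#' "increased"/"decreased", everything else "unaltered". A feature at or
#' below the detection limit in control but detected in treatment is
#' "increased" with marker "new"; the reverse is "decreased" with marker
#' "lost".
#'
#' @param control_mean,treatment_mean mean abundances (>= 0); vectors are
#'   processed elementwise.
#' @param fold_threshold fold-change threshold (strict inequality).
#' @param detection_limit abundance at or below which a feature counts as
#'   undetected (default 0).
#' @return data.frame with columns ratio (treatment/control), direction
#'   ("increased"/"decreased"/"unaltered") and marker ("new"/"lost"/NA).
#' @export
#' @examples
#' classify_modulation(0.01, 0.06)$direction  # "increased"
classify_modulation <- function(control_mean, treatment_mean,
                                fold_threshold = 5, detection_limit = 0) {
  if (any(control_mean < 0) || any(treatment_mean < 0)) {
    stop_input("mean abundances must be >= 0")
  }
  if (fold_threshold <= 1) stop_input("`fold_threshold` must be > 1")
  k <- max(length(control_mean), length(treatment_mean))
  control_mean <- rep_len(control_mean, k)
  treatment_mean <- rep_len(treatment_mean, k)

  ratio <- ifelse(control_mean > 0, treatment_mean / control_mean,
                  ifelse(treatment_mean > 0, Inf, NA_real_))
  direction <- rep("unaltered", k)
  marker <- rep(NA_character_, k)

  ctrl_det <- control_mean > detection_limit
  trt_det <- treatment_mean > detection_limit
  new <- !ctrl_det & trt_det
  lost <- ctrl_det & !trt_det
  both <- ctrl_det & trt_det

  direction[new] <- "increased"; marker[new] <- "new"
  direction[lost] <- "decreased"; marker[lost] <- "lost"
  up <- both & (treatment_mean > fold_threshold * control_mean)
  down <- both & (control_mean > fold_threshold * treatment_mean)
  direction[up] <- "increased"
  direction[down] <- "decreased"

  data.frame(ratio = ratio, direction = direction, marker = marker,
             stringsAsFactors = FALSE)
}

## Shared worker: features x samples value matrix + metadata -> contrasts.
differential_worker <- function(values, meta, control, fold_threshold,
                                detection_limit, exact_limit) {
  if (!control %in% meta$condition) {
    stop_input("control condition '%s' absent from metadata", control)
  }
  reps <- table(meta$condition)
  if (any(reps < 2)) {
    stop_input("every condition needs >= 2 replicates (offending: %s)",
               paste(names(reps)[reps < 2], collapse = ", "))
  }
  conditions <- setdiff(unique(meta$condition), control)
  ctrl_cols <- meta$sample_id[meta$condition == control]
  rows <- list()
  for (cond in conditions) {
    trt_cols <- meta$sample_id[meta$condition == cond]
    ctrl_mean <- rowMeans(values[, ctrl_cols, drop = FALSE])
    trt_mean <- rowMeans(values[, trt_cols, drop = FALSE])
    cls <- classify_modulation(ctrl_mean, trt_mean, fold_threshold,
                               detection_limit)
    tests <- lapply(seq_len(nrow(values)), function(i) {
      mann_whitney_exact(values[i, trt_cols], values[i, ctrl_cols],
                         exact_limit = exact_limit)
    })
    p <- vapply(tests, function(t) t$p.value, numeric(1))
    rows[[cond]] <- data.frame(
      feature = rownames(values), condition = cond,
      control_mean = ctrl_mean, treatment_mean = trt_mean,
      ratio = cls$ratio, direction = cls$direction, marker = cls$marker,
      U = vapply(tests, function(t) unname(t$statistic), numeric(1)),
      p_value = p,
      p_adj = p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("diff_table", "data.frame"))
}

#' Differential table of features against control cultures
#'
#' For every feature (taxon or phenotype) and every non-control condition:
#' replicate means, fold-modulation classification and the exact two-tailed
#' Mann-Whitney p of the replicate values against the control replicates.
#' Results are emitted for every feature (no silent filtering). A
#' Benjamini-Hochberg column (`p_adj`, per condition) accompanies the raw
#' p values but never gates output.
#'
#' @param x an `abund_table` (counts are converted to relative abundance
#'   first) or a `cpi_table` with sample metadata.
#' @param control control condition label.
#' @param fold_threshold,detection_limit see [classify_modulation()].
#' @param exact_limit see [mann_whitney_exact()].
#' @param ... passed between methods.
#' @return data.frame of class `diff_table`.
#' @export
differential_table <- function(x, ...) UseMethod("differential_table")

#' @rdname differential_table
#' @export
differential_table.abund_table <- function(x, control = "control",
                                           fold_threshold = 5,
                                           detection_limit = 0,
                                           exact_limit = 12L, ...) {
  if (is.null(x$meta)) stop_input("abundance table has no sample metadata")
  rel <- to_relative(x)
  differential_worker(rel$mat, rel$meta, control, fold_threshold,
                      detection_limit, exact_limit)
}

#' @rdname differential_table
#' @export
differential_table.cpi_table <- function(x, control = "control",
                                         fold_threshold = 5,
                                         detection_limit = 0,
                                         exact_limit = 12L, ...) {
  meta <- attr(x, "meta")
  if (is.null(meta)) stop_input("CPI table has no sample metadata")
  values <- t(unclass(x))       # phenotypes x samples
  differential_worker(values, meta, control, fold_threshold,
                      detection_limit, exact_limit)
}

#' Summarize modulation counts per condition
#'
#' Counts of increased, decreased, altered (= increased + decreased) and
#' unaltered features per condition, the summary behind
#' increased/decreased/unaltered bar charts.
#'
#' @param diff a `diff_table`.
#' @return data.frame with one row per condition.
#' @export
modulation_summary <- function(diff) {
  stopifnot(inherits(diff, "diff_table"))
  conds <- unique(diff$condition)
  out <- do.call(rbind, lapply(conds, function(cond) {
    d <- diff[diff$condition == cond, ]
    inc <- sum(d$direction == "increased")
    dec <- sum(d$direction == "decreased")
    data.frame(condition = cond, increased = inc, decreased = dec,
               altered = inc + dec,
               unaltered = sum(d$direction == "unaltered"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
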