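#' Construct a survival cohort
#'
#' One cancer/platform combination: per-patient follow-up times and event
#' indicators together with a genes x patients expression matrix.
#'
#' @param cohort_id Identifier.
#' @param expression Numeric matrix, genes x patients (no missing values).
#' @param time Non-negative follow-up times, one per patient.
#' @param event 0/1 event indicators, one per patient.
#' @return Object of class `cohort_survival`.
#' @export
cohort_survival <- function(cohort_id, expression, time, event) {
  expression <- as.matrix(expression)
  if (anyNA(expression)) stop("cohort_survival: missing expression values")
  if (is.null(rownames(expression))) stop("cohort_survival: expression needs gene rownames")
  n <- ncol(expression)
  stopifnot(length(time) == n, length(event) == n)
  if (any(time < 0)) stop("cohort_survival: negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("cohort_survival: event must be 0/1")
  structure(list(cohort_id = as.character(cohort_id), expression = expression,
                 time = as.numeric(time), event = as.integer(event)),
            class = "cohort_survival")
}

#' @export
print.cohort_survival <- function(x, ...) {
  cat("cohort_survival '", x$cohort_id, "': ", nrow(x$expression), " genes x ",
      ncol(x$expression), " patients, ", sum(x$event), " events\n", sep = "")
  invisible(x)
}

#' Per-gene proportional-hazards score tests for one cohort
#'
#' For each gene, the Cox proportional-hazards score (log-rank-type) test of
#' the standardized continuous expression value against survival, with the
#' Breslow convention for tied event times. The score test at beta = 0 is
#' computed in closed form for all genes at once, which makes genome-wide
#' screens across many cohorts fast; on tie-free data it is identical to the
#' score test reported by a Cox model fit. The direction is the sign of the
#' score (positive: higher expression, higher hazard).
#'
#' @param cohort A [cohort_survival] with at least 2 events.
#' @return Data frame with `gene`, `chi2`, `p`, `direction`; constant genes
#'   get `NA`.
#' @export
gene_survival_pvalues <- function(cohort) {
  ev_total <- sum(cohort$event)
  if (ev_total == 0L) stop("gene_survival_pvalues: no events in cohort")
  if (ev_total < 2L) stop("gene_survival_pvalues: fewer than 2 events")
  x <- cohort$expression
  sd_ <- sqrt(row_vars(x))
  const <- sd_ == 0
  xz <- (x - rowMeans(x)) / ifelse(const, 1, sd_)
  ord <- order(cohort$time, decreasing = TRUE)
  xo <- xz[, ord, drop = FALSE]
  to <- cohort$time[ord]
  evo <- cohort$event[ord]
  n <- length(to)
  # prefix sums over the risk sets (patients sorted by decreasing time:
  # the first k patients are exactly the risk set of the k-th time value)
  tri <- upper.tri(matrix(0, n, n), diag = TRUE)
  storage.mode(tri) <- "double"
  s1 <- xo %*% tri
  s2 <- (xo^2) %*% tri
  U <- numeric(nrow(x)); V <- numeric(nrow(x))
  for (t in unique(to[evo == 1L])) {
    k <- sum(to >= t)                      # risk set size
    at <- which(to == t & evo == 1L)
    d <- length(at)
    sx <- if (d == 1L) xo[, at] else rowSums(xo[, at, drop = FALSE])
    m1 <- s1[, k] / k
    U <- U + sx - d * m1
    V <- V + d * (s2[, k] / k - m1^2)
  }
  chi2 <- ifelse(V > 0, U^2 / V, NA_real_)
  chi2[const] <- NA_real_
  data.frame(gene = rownames(x), chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             direction = ifelse(const | V == 0, NA_real_, sign(U)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine independent p-values by Fisher's method
#'
#' `X = -2 * sum(log(p))` is referred to the upper tail of a chi-squared
#' distribution with `2k` degrees of freedom. With a single p-value the
#' combination is the identity. Zero p-values are clipped to the smallest
#' positive representable value with a warning.
#'
#' @param p Numeric vector of p-values in (0, 1], length >= 1.
#' @return The combined p-value.
#' @export
combine_pvalues <- function(p) {
  stopifnot(length(p) >= 1L)
  if (any(p < 0 | p > 1)) stop("combine_pvalues: p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("combine_pvalues: zero p-value(s) clipped")
    p[p == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

#' Gene-survival associations across cohorts
#'
#' Runs [gene_survival_pvalues] on every cohort, combines each gene's
#' per-cohort p-values with Fisher's method, and adjusts the combined
#' p-values by Benjamini-Hochberg. Only genes with expression available in
#' every cohort (and a defined test everywhere) enter the ranking.
#'
#' @param cohorts List of [cohort_survival] objects.
#' @return Data frame of class `survival_association` with `gene`,
#'   `combined_p`, `adjusted_combined_p` and one `p_<cohort_id>` column per
#'   cohort; per-cohort direction signs in attribute `"directions"`.
#' @export
survival_associations <- function(cohorts) {
  stopifnot(length(cohorts) >= 1L)
  tabs <- lapply(cohorts, gene_survival_pvalues)
  genes <- Reduce(intersect, lapply(tabs, `[[`, "gene"))
  if (length(genes) == 0L) stop("survival_associations: no shared genes")
  P <- sapply(tabs, function(t) t$p[match(genes, t$gene)])
  D <- sapply(tabs, function(t) t$direction[match(genes, t$gene)])
  P <- matrix(P, nrow = length(genes))
  ok <- rowSums(is.na(P)) == 0L
  if (any(!ok)) {
    message("survival_associations: dropped ", sum(!ok),
            " gene(s) with undefined tests")
    genes <- genes[ok]; P <- P[ok, , drop = FALSE]
    D <- matrix(D, ncol = ncol(P))[ok, , drop = FALSE]
  }
  Pc <- pmax(P, .Machine$double.xmin)
  X <- -2 * rowSums(log(Pc))
  combined <- stats::pchisq(X, df = 2 * ncol(P), lower.tail = FALSE)
  out <- data.frame(gene = genes, combined_p = combined,
                    adjusted_combined_p = stats::p.adjust(combined, "BH"),
                    stringsAsFactors = FALSE)
  pc <- as.data.frame(P)
  colnames(pc) <- paste0("p_", vapply(cohorts, `[[`, "", "cohort_id"))
  out <- cbind(out, pc)
  attr(out, "directions") <- D
  class(out) <- c("survival_association", "data.frame")
  out
}

#' Fold-enrichment of a candidate list among survival-associated genes
#'
#' Genes with combined p below `p_cutoff` form the survival set; the report
#' gives the fold-enrichment of the candidate list in that set relative to
#' the universe, with a hypergeometric tail p-value. When a network is
#' supplied, the candidate list is first replaced by the union of its direct
#' network neighbors (the candidates themselves excluded), which tests
#' whether the *neighborhood* of the list is prognostic.
#'
#' @param candidates A [gene_set], a subset of the universe.
#' @param associations A `survival_association` data frame (or any data
#'   frame with `gene` and `combined_p`).
#' @param p_cutoff Combined-p threshold defining survival association.
#' @param universe A [gene_set]: the genes over which enrichment is judged.
#' @param expand_neighbors Optional [gene_network] switching on neighbor
#'   expansion.
#' @return List of class `enrichment_report`: `list_id`, `n_list`,
#'   `n_list_survival`, `universe_n`, `universe_survival`, `fold`, `p`,
#'   `flagged` (TRUE when the fold is undefined: empty survival set or empty
#'   expanded list).
#' @export
survival_fold_enrichment <- function(candidates, associations, p_cutoff,
                                     universe, expand_neighbors = NULL) {
  candidates <- as_gene_set(candidates, "candidates")
  universe <- as_gene_set(universe, "universe")
  if (!all(candidates$members %in% universe$members)) {
    stop("survival_fold_enrichment: candidates must be a subset of the universe")
  }
  list_id <- candidates$id
  members <- candidates$members
  if (!is.null(expand_neighbors)) {
    members <- intersect(network_neighbors(expand_neighbors, members),
                         universe$members)
    list_id <- paste0(list_id, "_neighbors")
    if (length(members) == 0L) {
      warning("survival_fold_enrichment: expanded list has no network presence")
      return(structure(list(list_id = list_id, n_list = 0L,
                            n_list_survival = 0L,
                            universe_n = length(universe$members),
                            universe_survival = NA_integer_,
                            fold = NA_real_, p = NA_real_, flagged = TRUE),
                       class = "enrichment_report"))
    }
  }
  assoc_genes <- normalize_symbols(associations$gene)
  in_univ <- assoc_genes %in% universe$members
  surv <- assoc_genes[in_univ & associations$combined_p < p_cutoff]
  n_u <- length(universe$members)
  n_us <- length(surv)
  n_l <- length(members)
  n_ls <- length(intersect(members, surv))
  if (n_us == 0L) {
    warning("survival_fold_enrichment: empty survival set, fold undefined")
    fold <- NA_real_; p <- NA_real_; flagged <- TRUE
  } else {
    fold <- (n_ls / n_l) / (n_us / n_u)
    p <- stats::phyper(n_ls - 1L, n_us, n_u - n_us, n_l, lower.tail = FALSE)
    flagged <- FALSE
  }
  structure(list(list_id = list_id, n_list = n_l, n_list_survival = n_ls,
                 universe_n = n_u, universe_survival = n_us,
                 fold = fold, p = p, flagged = flagged),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("enrichment_report '", x$list_id, "': ", x$n_list_survival, "/",
      x$n_list, " vs ", x$universe_survival, "/", x$universe_n,
      sprintf(" -> fold %.2f (p = %.3g)\n", x$fold, x$p), sep = "")
  invisible(x)
}
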