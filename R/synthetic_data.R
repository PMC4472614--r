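#' Parameters of a synthetic confrontation study
#'
#' The defaults emulate the study design the analysis assumes: 8 fibroblast
#' lines, each measured before and after confrontation (16 paired samples);
#' about 45% of ~20,000 genes forming a low-mean/low-variance "absent"
#' cluster straddling the filter thresholds with a clear margin (mean 3,
#' variance 0.05 against thresholds 4 and 0.1); expressed genes with a per
#' gene-and-line baseline of Normal(8, 1) log2 units and per-sample noise of
#' sd 0.5; 300 confrontation-responsive genes shifted by 1 log2 unit in the
#' post samples of all lines; 300 inhibition-related genes shifted in the 4
#' high-inhibition lines (both conditions) by 1.5 log2 units -- a line-level
#' contrast that must stand out against the between-line baseline variance;
#' a fraction of co-expressed genes loading on a shared latent factor, so
#' that the "chance" correlation baseline is non-zero as in real data; and a
#' 500-node / 2000-edge scale-free network for enrichment tests.
#'
#' @param n_genes,n_lines,absent_fraction,absent_mean,absent_var,
#'   confrontation_effect,n_confrontation_degs,inhibition_effect,
#'   n_inhibition_degs,noise_sd,baseline_mean,baseline_sd,
#'   coexpressed_fraction,coexpressed_loading,network_n_nodes,
#'   network_n_edges,planted_link_factor,seed Study parameters; see
#'   Details/defaults.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 20000L, n_lines = 8L,
                       absent_fraction = 0.45, absent_mean = 3,
                       absent_var = 0.05,
                       confrontation_effect = 1, n_confrontation_degs = 300L,
                       inhibition_effect = 1.5, n_inhibition_degs = 300L,
                       noise_sd = 0.5, baseline_mean = 8, baseline_sd = 1,
                       coexpressed_fraction = 0.10, coexpressed_loading = 2,
                       network_n_nodes = 500L, network_n_edges = 2000L,
                       planted_link_factor = 3, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
               absent_fraction = absent_fraction, absent_mean = absent_mean,
               absent_var = absent_var,
               confrontation_effect = confrontation_effect,
               n_confrontation_degs = as.integer(n_confrontation_degs),
               inhibition_effect = inhibition_effect,
               n_inhibition_degs = as.integer(n_inhibition_degs),
               noise_sd = noise_sd, baseline_mean = baseline_mean,
               baseline_sd = baseline_sd,
               coexpressed_fraction = coexpressed_fraction,
               coexpressed_loading = coexpressed_loading,
               network_n_nodes = as.integer(network_n_nodes),
               network_n_edges = as.integer(network_n_edges),
               planted_link_factor = planted_link_factor,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_genes > 0, n_lines > 0, n_confrontation_degs > 0,
              n_inhibition_degs > 0, network_n_nodes > 0, network_n_edges > 0,
              noise_sd > 0, absent_var > 0)
    stopifnot(absent_fraction >= 0, absent_fraction <= 1,
              coexpressed_fraction >= 0, coexpressed_fraction <= 1)
    n_expressed <- n_genes - round(absent_fraction * n_genes)
    if (n_confrontation_degs + n_inhibition_degs > n_expressed) {
      stop("synth_spec: planted effect counts exceed the expressed gene count")
    }
  })
  structure(spec, class = "synth_spec")
}

#' Synthetic scale-free gene network
#'
#' Static power-law (fitness-based preferential attachment) random graph
#' with exactly the requested edge count: simple, heavy-tailed degrees, and
#' a giant component at the default density. Node names are synthetic gene
#' symbols `G0001`, `G0002`, ...; isolated vertices do not enter the
#' returned network.
#'
#' @param n_nodes,n_edges Graph size; `n_edges` must not exceed
#'   `n_nodes * (n_nodes - 1) / 2`.
#' @param seed Integer seed (generation is deterministic).
#' @param exponent Power-law exponent of the degree fitness (default 2.3).
#' @param node_names Optional character vector of length `n_nodes` to use as
#'   node names (e.g. gene symbols of an expression study).
#' @return A [gene_network].
#' @export
synth_network <- function(n_nodes, n_edges, seed = 1L, exponent = 2.3,
                          node_names = NULL) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("synth_network: infeasible edge count for a simple graph")
  }
  if (is.null(node_names)) {
    node_names <- sprintf("G%04d", seq_len(n_nodes))
  }
  stopifnot(length(node_names) == n_nodes, !anyDuplicated(node_names))
  set.seed(seed)
  g <- igraph::sample_fitness_pl(n_nodes, n_edges, exponent.out = exponent,
                                 loops = FALSE, multiple = FALSE)
  igraph::V(g)$name <- node_names
  gene_network(igraph::as_edgelist(g, names = TRUE), quiet = TRUE)
}

#' Composite synthetic study: expression, network, pathways, planted links
#'
#' Assembles a complete testbed for the two end-to-end analyses: a paired
#' expression study from [synth_expression]; a scale-free network whose
#' nodes are study genes, including a fixed quota of the planted
#' confrontation and inhibition DEGs; a functional gene set collection
#' sampled from the network nodes, whose first two sets are "pathways" with
#' cross-link excess (factor `spec$planted_link_factor`) planted towards the
#' confrontation truth set and the inhibition truth set respectively.
#'
#' @param spec A [synth_spec].
#' @param n_pathways Number of functional gene sets (>= 2).
#' @param pathway_size Members per set.
#' @param degs_in_network How many planted DEGs of each contrast are forced
#'   onto the network.
#' @return List with `study`, `truth` (as in [synth_expression], plus
#'   `confrontation_pathway` and `inhibition_pathway` ids), `network` and
#'   `fgs` (named list of [gene_set]).
#' @export
synth_full_study <- function(spec = synth_spec(), n_pathways = 20L,
                             pathway_size = 30L, degs_in_network = 60L) {
  stopifnot(n_pathways >= 2L)
  sim <- synth_expression(spec)
  set.seed(spec$seed + 1L)
  conf_net <- sample(sim$truth$confrontation, degs_in_network)
  inh_net <- sample(sim$truth$inhibition, degs_in_network)
  expressed <- setdiff(rownames(sim$study$matrix), sim$truth$absent)
  rest <- sample(setdiff(expressed, c(conf_net, inh_net)),
                 spec$network_n_nodes - 2L * degs_in_network)
  node_names <- sample(c(conf_net, inh_net, rest))
  network <- synth_network(spec$network_n_nodes, spec$network_n_edges,
                           seed = spec$seed + 2L, node_names = node_names)
  set.seed(spec$seed + 3L)
  fgs_pool <- setdiff(network$nodes, c(conf_net, inh_net))
  fgs <- lapply(seq_len(n_pathways), function(i) {
    id <- if (i == 1L) "CONF_PATHWAY" else if (i == 2L) "INHIB_PATHWAY"
          else sprintf("PATHWAY_%02d", i)
    gene_set(id, sample(fgs_pool, pathway_size))
  })
  names(fgs) <- vapply(fgs, `[[`, "", "id")
  network <- plant_cross_links(network, gene_set("conf", conf_net),
                               fgs[["CONF_PATHWAY"]],
                               factor = spec$planted_link_factor,
                               seed = spec$seed + 4L)
  network <- plant_cross_links(network, gene_set("inh", inh_net),
                               fgs[["INHIB_PATHWAY"]],
                               factor = spec$planted_link_factor,
                               seed = spec$seed + 5L)
  sim$truth$confrontation_pathway <- "CONF_PATHWAY"
  sim$truth$inhibition_pathway <- "INHIB_PATHWAY"
  list(study = sim$study, truth = sim$truth, network = network, fgs = fgs)
}

#' Plant excess cross-links between two gene sets
#'
#' Rewires edges so that the observed AGS-FGS cross-link count is
#' approximately `factor` times the configuration-model expectation, while
#' conserving the total edge count exactly: new cross edges are added
#' between random members of the two sets and an equal number of edges
#' uninvolved with either set is removed. Degrees drift by construction (the
#' drift is reported in a message); because the expectation itself moves
#' with the degree sums, the target is re-evaluated iteratively until the
#' observed/expected ratio reaches the factor.
#'
#' @param network A [gene_network].
#' @param ags,fgs [gene_set] objects (members outside the network are
#'   ignored).
#' @param factor Desired observed/expected ratio (>= 1); `factor = 1`
#'   returns the network unchanged.
#' @param seed Integer seed.
#' @return A [gene_network] with the same `n_total`.
#' @export
plant_cross_links <- function(network, ags, fgs, factor, seed = 1L) {
  if (factor < 1) stop("plant_cross_links: factor must be >= 1")
  ags <- as_gene_set(ags, "ags"); fgs <- as_gene_set(fgs, "fgs")
  if (factor == 1) return(network)
  set.seed(seed)
  deg0 <- network$degree
  net <- network
  a_in <- intersect(ags$members, network$nodes)
  f_in <- intersect(fgs$members, network$nodes)
  if (length(a_in) == 0L || length(f_in) == 0L) {
    warning("plant_cross_links: a set has no network presence; returning unchanged")
    return(network)
  }
  prev_need <- Inf
  for (iter in 1:30) {
    obs <- count_cross_links(net, ags, fgs)
    expd <- expected_cross_links(net, ags, fgs)
    need <- ceiling(factor * expd) - obs
    if (need <= 0L) break
    if (need >= prev_need) {
      # planting inflates the degree sums (and so the expectation) at least
      # as fast as it adds cross links: no fixed point for these set sizes
      warning("plant_cross_links: expectation inflates as fast as planting; ",
              "best effort at ratio ", sprintf("%.2f", obs / expd))
      break
    }
    prev_need <- need
    existing <- paste(net$edges[, 1], net$edges[, 2], sep = "\r")
    new_edges <- matrix(character(0), ncol = 2)
    guard <- 0L
    while (nrow(new_edges) < need && guard < 50L) {
      guard <- guard + 1L
      a <- sample(a_in, need, replace = TRUE)
      b <- sample(f_in, need, replace = TRUE)
      ok <- a != b
      lo <- pmin(a, b); hi <- pmax(a, b)
      key <- paste(lo, hi, sep = "\r")
      ok <- ok & !key %in% existing & !duplicated(key)
      new_edges <- rbind(new_edges, cbind(lo[ok], hi[ok]))
      new_edges <- new_edges[!duplicated(paste(new_edges[, 1], new_edges[, 2],
                                               sep = "\r")), , drop = FALSE]
    }
    k <- min(nrow(new_edges), need)
    if (k == 0L) {
      warning("plant_cross_links: no addable cross edges left; best effort")
      break
    }
    new_edges <- new_edges[seq_len(k), , drop = FALSE]
    untouched <- !(net$edges[, 1] %in% c(a_in, f_in)) &
      !(net$edges[, 2] %in% c(a_in, f_in))
    removable <- which(untouched)
    if (length(removable) < k) {
      warning("plant_cross_links: removing set-adjacent edges; degree drift grows")
      a1 <- net$edges[, 1] %in% a_in; a2 <- net$edges[, 2] %in% a_in
      f1 <- net$edges[, 1] %in% f_in; f2 <- net$edges[, 2] %in% f_in
      non_cross <- !((a1 & f2) | (a2 & f1))
      removable <- union(removable, which(non_cross))
    }
    if (length(removable) < k) {
      warning("plant_cross_links: target unreachable; best effort")
      k <- length(removable)
      new_edges <- new_edges[seq_len(k), , drop = FALSE]
    }
    drop_idx <- sample(removable, k)
    net <- gene_network(rbind(net$edges[-drop_idx, , drop = FALSE], new_edges),
                        quiet = TRUE)
  }
  common <- intersect(names(deg0), names(net$degree))
  drift <- sum(abs(net$degree[common] - deg0[common])) +
    sum(deg0[setdiff(names(deg0), common)]) +
    sum(net$degree[setdiff(names(net$degree), common)])
  message("plant_cross_links: total absolute degree drift ", drift,
          " over ", length(deg0), " nodes")
  net
}

#' Synthetic paired confrontation expression study
#'
#' Generates the `2 * n_lines` samples of a paired pre/post design with
#' ground-truth labels: an absent cluster, expressed genes with per
#' gene-and-line baselines, a latent co-expression factor, confrontation
#' effects (post samples of all lines, random sign per gene) and inhibition
#' effects (all samples of the high-inhibition half of the lines, random
#' sign per gene). The first and the (n_lines/2 + 1)-th line are labeled
#' in vitro, the rest ex vivo, mirroring a design with one immortalized
#' line in each inhibition class.
#'
#' @param spec A [synth_spec].
#' @return List with `study` (an [expression_study]) and `truth` (lists of
#'   gene ids: `absent`, `confrontation`, `inhibition`, `coexpressed`, plus
#'   the planted signs).
#' @export
synth_expression <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  nl <- spec$n_lines
  ns <- 2L * nl
  genes <- sprintf("SG%05d", seq_len(ng))
  n_abs <- round(spec$absent_fraction * ng)
  absent <- genes[seq_len(n_abs)]
  expressed <- setdiff(genes, absent)
  conf <- sample(expressed, spec$n_confrontation_degs)
  inhib <- sample(setdiff(expressed, conf), spec$n_inhibition_degs)
  pool <- setdiff(expressed, c(conf, inhib))
  coex <- sample(pool, round(spec$coexpressed_fraction * length(expressed)))

  lines <- sprintf("FL%d", seq_len(nl))
  high <- lines[seq_len(nl %/% 2)]
  samples <- data.frame(
    sample_id = c(paste0(lines, "_pre"), paste0(lines, "_post")),
    line_id = rep(lines, 2L),
    condition = rep(c("pre", "post"), each = nl),
    inhibition = rep(ifelse(lines %in% high, "high", "low"), 2L),
    origin = rep(ifelse(lines %in% lines[c(1L, nl %/% 2 + 1L)],
                        "in_vitro", "ex_vivo"), 2L),
    stringsAsFactors = FALSE
  )

  x <- matrix(0, nrow = ng, ncol = ns, dimnames = list(genes, samples$sample_id))
  x[absent, ] <- stats::rnorm(n_abs * ns, spec$absent_mean,
                              sqrt(spec$absent_var))
  ne <- length(expressed)
  base <- matrix(stats::rnorm(ne * nl, spec$baseline_mean, spec$baseline_sd),
                 nrow = ne)              # per gene-and-line baseline
  x[expressed, ] <- base[, rep(seq_len(nl), 2L)] +
    stats::rnorm(ne * ns, 0, spec$noise_sd)

  f <- stats::rnorm(ns)                  # shared latent sample factor
  loading <- sample(c(-1, 1), length(coex), replace = TRUE) *
    spec$coexpressed_loading
  x[coex, ] <- x[coex, ] + outer(loading, f)

  conf_sign <- sample(c(-1, 1), length(conf), replace = TRUE)
  post_cols <- samples$condition == "post"
  x[conf, post_cols] <- x[conf, post_cols] +
    conf_sign * spec$confrontation_effect

  inh_sign <- sample(c(-1, 1), length(inhib), replace = TRUE)
  high_cols <- samples$inhibition == "high"
  x[inhib, high_cols] <- x[inhib, high_cols] +
    inh_sign * spec$inhibition_effect

  list(study = expression_study(x, samples),
       truth = list(absent = absent, confrontation = conf,
                    inhibition = inhib, coexpressed = coex,
                    confrontation_sign = conf_sign,
                    inhibition_sign = inh_sign,
                    high_lines = high))
}

#' Synthetic TF-target map with planted expression correlation
#'
#' Samples transcription factors and targets among the expressed genes of a
#' study and plants, for a fraction of the pairs, a true regulatory signal:
#' the target profile is rewritten as its own mean plus the centered TF
#' profile plus noise. Returns the map, the modified study and the
#' ground-truth labels. With `correlated_fraction = 0` the map is a pure
#' null and the correlated-pair excess is ~1.
#'
#' @param study An [expression_study].
#' @param n_tfs,targets_per_tf Map dimensions.
#' @param correlated_fraction Probability that a pair carries a planted
#'   correlation.
#' @param noise_sd Sd of the noise added to planted target profiles
#'   (default 0.5; together with the typical TF profile variance this gives
#'   planted correlations around 0.9).
#' @param seed Integer seed.
#' @param min_mean Genes with mean below this are not eligible (default 4,
#'   i.e. only expressed genes).
#' @return List with `tf_map` ([tf_target_map]), `study` (profiles of
#'   planted targets rewritten) and `truth` (logical vector over map rows).
#' @export
synth_tf_targets <- function(study, n_tfs = 50L, targets_per_tf = 12L,
                             correlated_fraction = 0.10, noise_sd = 0.5,
                             seed = 1L, min_mean = 4) {
  set.seed(seed)
  pool <- rownames(study$matrix)[rowMeans(study$matrix) >= min_mean]
  if (length(pool) < n_tfs * (1 + targets_per_tf)) {
    stop("synth_tf_targets: not enough expressed genes for the requested map")
  }
  tfs <- sample(pool, n_tfs)
  target_pool <- setdiff(pool, tfs)
  tf_col <- rep(tfs, each = targets_per_tf)
  target_col <- unlist(lapply(seq_len(n_tfs), function(i) {
    sample(target_pool, targets_per_tf)
  }))
  planted <- stats::runif(length(tf_col)) < correlated_fraction
  planted[duplicated(target_col) & planted] <- FALSE  # one planting per target
  x <- study$matrix
  ns <- ncol(x)
  for (i in which(planted)) {
    tfp <- x[tf_col[i], ]
    x[target_col[i], ] <- mean(x[target_col[i], ]) + (tfp - mean(tfp)) +
      stats::rnorm(ns, 0, noise_sd)
  }
  map <- tf_target_map(tf_col, target_col)
  # map construction dedups ordered pairs; keep truth aligned
  key <- paste(tf_col, target_col, sep = "\r")
  truth <- planted[!duplicated(key)]
  list(tf_map = map, study = expression_study(x, study$samples),
       truth = truth)
}

#' Synthetic survival cohorts with planted prognostic genes
#'
#' Each cohort draws an exponential baseline hazard modulated by a latent
#' per-patient risk score; prognostic genes are correlated with that score
#' (correlation `rho`) so that each carries a marginal hazard ratio of
#' `hazard_ratio` per expression standard deviation. Censoring is
#' independent exponential, tuned to the requested rate. The same
#' prognostic gene set is shared across cohorts (patients are independent),
#' mirroring a meta-analysis across cancer/platform combinations.
#'
#' @param n_cohorts,n_patients,n_genes Cohort dimensions.
#' @param n_prognostic Number of prognostic genes.
#' @param hazard_ratio Marginal hazard ratio per expression sd (1 = null).
#' @param censor_rate Expected censoring fraction in [0, 1).
#' @param seed Integer seed.
#' @param rho Correlation between a prognostic gene and the latent risk
#'   score.
#' @return List with `cohorts` (list of [cohort_survival]) and `prognostic`
#'   (character vector of planted gene ids).
#' @export
synth_survival <- function(n_cohorts = 6L, n_patients = 150L,
                           n_genes = 1000L, n_prognostic = 150L,
                           hazard_ratio = 2, censor_rate = 0.3, seed = 1L,
                           rho = 0.7) {
  stopifnot(n_cohorts >= 1L, n_patients >= 2L, n_genes >= 1L,
            n_prognostic <= n_genes, hazard_ratio > 0,
            censor_rate >= 0, censor_rate < 1)
  set.seed(seed)
  genes <- sprintf("SG%05d", seq_len(n_genes))
  prognostic <- sort(sample(genes, n_prognostic))
  beta <- log(hazard_ratio) / rho
  cens_rate <- if (censor_rate > 0) censor_rate / (1 - censor_rate) else 0
  cohorts <- lapply(seq_len(n_cohorts), function(ci) {
    r <- stats::rnorm(n_patients)
    x <- matrix(stats::rnorm(n_genes * n_patients), nrow = n_genes,
                dimnames = list(genes, sprintf("P%03d", seq_len(n_patients))))
    ip <- genes %in% prognostic
    if (any(ip)) {
      x[ip, ] <- rho * matrix(rep(r, each = sum(ip)), nrow = sum(ip)) +
        sqrt(1 - rho^2) * x[ip, , drop = FALSE]
    }
    tdeath <- stats::rexp(n_patients) / exp(beta * r)
    if (cens_rate > 0) {
      tcens <- stats::rexp(n_patients, rate = cens_rate)
      time <- pmin(tdeath, tcens)
      event <- as.integer(tdeath <= tcens)
    } else {
      time <- tdeath
      event <- rep(1L, n_patients)
    }
    cohort_survival(sprintf("C%02d", ci), x, time, event)
  })
  list(cohorts = cohorts, prognostic = prognostic)
}
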