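#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the planted-truth simulation that stands in for the
#' real inputs of the cascade (multi-cohort miRNA expression, tumor/normal
#' mRNA matrices, target-prediction votes, a confidence-weighted interaction
#' network, pathway gene sets, 3'UTR sequences and a clinical table). Every
#' generator derives its own RNG stream from `seed`, so the same seed gives
#' byte-identical outputs regardless of the order generators are called in.
#'
#' @param seed integer master RNG seed.
#' @param n_studies number of case/control miRNA expression studies.
#' @param planted_smd true standardized mean difference of the miRNA marker
#'   (tumor minus normal, in units of the within-group SD).
#' @param study_n_tumor,study_n_normal per-study group sizes (recycled to
#'   `n_studies`); the defaults follow the four published case/control
#'   profiling studies of this miRNA in cervical tissue (19/19, 30/26, 8/8,
#'   10/10).
#' @param mu_normal,sigma log2-scale mean of the marker in normal tissue and
#'   the common within-group SD.
#' @param n_genes gene-universe size.
#' @param de_fraction fraction of the universe planted as differentially
#'   expressed; exactly `floor(de_fraction * n_genes)` genes are planted.
#' @param lfc_effect mean |log2 fold change| of planted DE genes.
#' @param de_n_tumor,de_n_normal group sizes of the tumor/normal matrix.
#' @param prop_up probability that a planted DE gene is upregulated.
#' @param n_databases number of target-prediction databases (12 by default).
#' @param db_sensitivity,db_specificity per-database vote probabilities on
#'   true targets and non-targets.
#' @param graph_nodes,attach_edges interaction-network size and the number of
#'   preferential-attachment edges each new node brings.
#' @param hub_module_size size of the planted near-clique module.
#' @param hub_edge_prob edge probability inside the planted module.
#' @param n_pathways,pathway_size_range,overlap_rate pathway-collection
#'   structure; `overlap_rate` is the fraction of each crosstalk-cluster
#'   pathway drawn from a shared gene pool.
#' @param n_anchors number of planted anchor genes (the ground-truth key
#'   genes; each is a member of the three designated pathways).
#' @param utr_length 3'UTR length in nucleotides.
#' @param n_planted_sites seed sites planted per positive UTR.
#' @param n_validation_studies,validation_n,validation_shift cross-cohort
#'   validation panel used by the key-gene meta-analysis: number of studies,
#'   per-arm sample size and the anchor shift in SD units.
#' @param n_clinical number of samples in the clinical table.
#' @param clinical_effect strength of the expression dependence of the
#'   planted ordinal covariate (lymph-node class), in SD units of the latent.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             n_studies = 4L,
                             planted_smd = 2.85,
                             study_n_tumor = c(19L, 30L, 8L, 10L),
                             study_n_normal = c(19L, 26L, 8L, 10L),
                             mu_normal = 8,
                             sigma = 1,
                             n_genes = 1200L,
                             de_fraction = 0.1,
                             lfc_effect = 3,
                             de_n_tumor = 30L,
                             de_n_normal = 30L,
                             prop_up = 0.95,
                             n_databases = 12L,
                             db_sensitivity = 0.9,
                             db_specificity = 0.95,
                             graph_nodes = 120L,
                             attach_edges = 2L,
                             hub_module_size = 15L,
                             hub_edge_prob = 0.9,
                             n_pathways = 25L,
                             pathway_size_range = c(10L, 18L),
                             overlap_rate = 0.6,
                             n_anchors = 3L,
                             utr_length = 300L,
                             n_planted_sites = 1L,
                             n_validation_studies = 9L,
                             validation_n = 20L,
                             validation_shift = 2,
                             n_clinical = 300L,
                             clinical_effect = 0.8) {
  cfg <- list(
    seed = as.integer(seed), n_studies = as.integer(n_studies),
    planted_smd = planted_smd,
    study_n_tumor = rep_len(as.integer(study_n_tumor), n_studies),
    study_n_normal = rep_len(as.integer(study_n_normal), n_studies),
    mu_normal = mu_normal, sigma = sigma,
    n_genes = as.integer(n_genes), de_fraction = de_fraction,
    lfc_effect = lfc_effect,
    de_n_tumor = as.integer(de_n_tumor), de_n_normal = as.integer(de_n_normal),
    prop_up = prop_up,
    n_databases = as.integer(n_databases),
    db_sensitivity = db_sensitivity, db_specificity = db_specificity,
    graph_nodes = as.integer(graph_nodes), attach_edges = as.integer(attach_edges),
    hub_module_size = as.integer(hub_module_size), hub_edge_prob = hub_edge_prob,
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    overlap_rate = overlap_rate, n_anchors = as.integer(n_anchors),
    utr_length = as.integer(utr_length),
    n_planted_sites = as.integer(n_planted_sites),
    n_validation_studies = as.integer(n_validation_studies),
    validation_n = as.integer(validation_n),
    validation_shift = validation_shift,
    n_clinical = as.integer(n_clinical), clinical_effect = clinical_effect
  )
  if (cfg$sigma <= 0) stop("invalid config: sigma must be positive")
  if (cfg$n_studies < 1L) stop("invalid config: need at least one study")
  if (any(c(cfg$study_n_tumor, cfg$study_n_normal) < 2L)) {
    stop("invalid config: group sizes must be at least 2 per arm")
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("invalid config: de_fraction must lie in [0, 1]")
  }
  if (cfg$db_sensitivity < 0 || cfg$db_sensitivity > 1 ||
      cfg$db_specificity < 0 || cfg$db_specificity > 1) {
    stop("invalid config: database sensitivity/specificity must lie in [0, 1]")
  }
  if (cfg$hub_module_size >= cfg$graph_nodes) {
    stop("invalid config: hub_module_size must be smaller than graph_nodes")
  }
  if (cfg$n_anchors > cfg$hub_module_size) {
    stop("invalid config: anchors must fit inside the hub module")
  }
  if (cfg$hub_module_size > floor(cfg$de_fraction * cfg$n_genes)) {
    stop("invalid config: the hub module must fit inside the planted DE set")
  }
  if (any(cfg$pathway_size_range < 1L)) {
    stop("invalid config: pathway sizes must be at least 1")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Gene names of the synthetic universe
#' @param n universe size.
#' @return character vector `g0001 ...`.
#' @export
gene_names <- function(n) sprintf("g%04d", seq_len(n))

#' Planted ground truth shared by all generators
#'
#' Fixes, deterministically for a given seed, the identities that every
#' generator agrees on: the DE gene set and its directions, the anchor genes
#' (ground-truth key genes), the hub-module membership, the true target set,
#' and the designated / crosstalk-cluster pathway ids.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `genes`, `de_genes`, `de_sign`, `anchors`,
#'   `module`, `targets`, `designated_pathways`, `cluster_pathways`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_stream(config$seed, 1L, {
    genes <- gene_names(config$n_genes)
    n_de <- floor(config$de_fraction * config$n_genes)
    de <- sort(sample(genes, n_de))
    anchors <- sort(sample(de, config$n_anchors))
    module <- sort(c(anchors,
                     sample(setdiff(de, anchors),
                            config$hub_module_size - config$n_anchors)))
    sign <- ifelse(stats::runif(n_de) < config$prop_up, 1, -1)
    names(sign) <- de
    sign[anchors] <- 1  # anchors emulate upregulated key genes
    n_extra <- min(length(setdiff(genes, de)), round(1.5 * n_de))
    targets <- sort(c(de, sample(setdiff(genes, de), n_extra)))
    list(genes = genes, de_genes = de, de_sign = sign, anchors = anchors,
         module = module, targets = targets,
         designated_pathways = sprintf("P%02d", 1:3),
         cluster_pathways = sprintf("P%02d", seq_len(min(9L, config$n_pathways))))
  })
}

# Constructor for one case/control expression dataset.
.expression_study <- function(values, group, log2 = FALSE, study_id = "study",
                              subgroup = NA_character_) {
  stopifnot(is.matrix(values), ncol(values) == length(group))
  structure(list(values = values,
                 group = factor(group, levels = c("normal", "tumor")),
                 log2 = log2, study_id = study_id, subgroup = subgroup),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study '%s'> %d genes x %d samples (%d tumor / %d normal), %s scale\n",
              x$study_id, nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal"),
              if (x$log2) "log2" else "raw"))
  invisible(x)
}

#' Simulate multi-study case/control expression of the miRNA marker
#'
#' Each study carries a `marker` row whose tumor group is shifted by
#' `planted_smd * sigma` on the log2 scale, plus null background genes.
#' Values are emitted on the raw scale (`2^x`) so the pipeline's log2 step is
#' exercised downstream. Alternating cancer-subtype labels are attached for
#' the subgroup analysis.
#'
#' @param config a [synthetic_config()].
#' @param n_background number of null genes per study besides the marker.
#' @param marker name of the marker row.
#' @return list of `expression_study` objects.
#' @export
gen_expression_studies <- function(config, n_background = 20L,
                                   marker = "miR-106b-5p") {
  stopifnot(inherits(config, "synthetic_config"))
  .with_stream(config$seed, 2L, {
    subtypes <- rep_len(c("squamous", "adeno"), config$n_studies)
    lapply(seq_len(config$n_studies), function(i) {
      n_t <- config$study_n_tumor[i]
      n_n <- config$study_n_normal[i]
      group <- rep(c("normal", "tumor"), c(n_n, n_t))
      log2_vals <- rbind(
        c(stats::rnorm(n_n, config$mu_normal, config$sigma),
          stats::rnorm(n_t, config$mu_normal +
                         config$planted_smd * config$sigma,
                       config$sigma)))
      if (n_background > 0) {
        log2_vals <- rbind(
          log2_vals,
          matrix(stats::rnorm(n_background * (n_n + n_t),
                              config$mu_normal, config$sigma),
                 nrow = n_background))
      }
      rownames(log2_vals) <- c(marker,
                               if (n_background > 0)
                                 sprintf("bg%03d", seq_len(n_background)))
      colnames(log2_vals) <- sprintf("s%d_%02d", i, seq_len(n_n + n_t))
      .expression_study(2^log2_vals, group, log2 = FALSE,
                        study_id = sprintf("study_%d", i),
                        subgroup = subtypes[i])
    })
  })
}

#' Simulate the tumor-versus-normal gene expression matrix
#'
#' Plants exactly `floor(de_fraction * n_genes)` DE genes, shifted by
#' `de_sign * lfc_effect` on the log2 scale in the tumor group; all other
#' genes are null. Output is raw-scale. Truth labels are returned alongside.
#'
#' @param config a [synthetic_config()].
#' @return list with `study` (an `expression_study`) and `truth`
#'   (`de_genes`, `de_sign`, `anchors`).
#' @export
gen_tumor_normal_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (floor(config$de_fraction * config$n_genes) < 1) {
    stop("invalid config: de_fraction * n_genes must be at least 1")
  }
  truth <- planted_truth(config)
  .with_stream(config$seed, 3L, {
    n_t <- config$de_n_tumor
    n_n <- config$de_n_normal
    genes <- truth$genes
    base <- stats::runif(config$n_genes, 4, 12)
    log2_vals <- matrix(stats::rnorm(config$n_genes * (n_n + n_t), base,
                                     config$sigma),
                        nrow = config$n_genes,
                        dimnames = list(genes,
                                        sprintf("tn_%02d", seq_len(n_n + n_t))))
    tumor_cols <- n_n + seq_len(n_t)
    shift <- config$lfc_effect * truth$de_sign
    log2_vals[truth$de_genes, tumor_cols] <-
      log2_vals[truth$de_genes, tumor_cols] + shift
    study <- .expression_study(2^log2_vals,
                               rep(c("normal", "tumor"), c(n_n, n_t)),
                               log2 = FALSE, study_id = "tumor_normal")
    list(study = study,
         truth = list(de_genes = truth$de_genes, de_sign = truth$de_sign,
                      anchors = truth$anchors))
  })
}

#' Simulate the multi-database target-prediction vote matrix
#'
#' Each database votes independently: Bernoulli(`db_sensitivity`) on true
#' targets, Bernoulli(`1 - db_specificity`) on everything else.
#'
#' @param config a [synthetic_config()].
#' @param true_targets character vector of true target genes; defaults to the
#'   planted truth.
#' @return integer 0/1 matrix, genes x databases, with the true-target set as
#'   attribute `true_targets`.
#' @export
gen_target_votes <- function(config, true_targets = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- planted_truth(config)
  if (is.null(true_targets)) true_targets <- truth$targets
  .with_stream(config$seed, 4L, {
    genes <- truth$genes
    p <- ifelse(genes %in% true_targets,
                config$db_sensitivity, 1 - config$db_specificity)
    votes <- matrix(stats::rbinom(length(genes) * config$n_databases, 1L,
                                  rep(p, config$n_databases)),
                    nrow = length(genes),
                    dimnames = list(genes,
                                    sprintf("db%02d", seq_len(config$n_databases))))
    attr(votes, "true_targets") <- true_targets
    votes
  })
}

#' Simulate the confidence-weighted interaction network
#'
#' A near-clique module of `hub_module_size` planted DE genes (pairwise edge
#' probability `hub_edge_prob`, confidence scores in `[0.75, 0.99]` so the
#' module survives the 0.7 confidence filter) seeds a scale-free backbone:
#' the remaining nodes (other DE genes padded with target-only genes) join
#' one at a time with `attach_edges` edges. Each module member is guaranteed
#' three dedicated partners among the first joiners (complex members carry
#' their own specific interactors); all other attachment is proportional to
#' current degree. A new node's first edge draws its confidence from
#' `[0.70, 0.95]` (its strongest-evidence interaction), further edges from
#' `[0.30, 0.90]`, emulating the low-skewed STRING confidence distribution.
#' The graph is simple (no loops, no multi-edges).
#'
#' @param config a [synthetic_config()].
#' @return list with `edges` (data.frame `node_a`, `node_b`, `score`),
#'   `nodes`, and `truth$module`.
#' @export
gen_ppi <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- planted_truth(config)
  .with_stream(config$seed, 5L, {
    module <- truth$module
    others <- setdiff(truth$de_genes, module)
    pad <- setdiff(truth$targets, truth$de_genes)
    extra_n <- config$graph_nodes - length(module) - length(others)
    if (extra_n < 0) {
      others <- sample(others, config$graph_nodes - length(module))
      extra_n <- 0L
    }
    rest <- sample(c(sample(others), sample(pad, min(extra_n, length(pad)))))
    # planted near-clique
    pairs <- utils::combn(module, 2)
    keep <- stats::runif(ncol(pairs)) < config$hub_edge_prob
    ea <- pairs[1, keep]; eb <- pairs[2, keep]
    sc <- stats::runif(sum(keep), 0.75, 0.99)
    # attachment of the remaining nodes: every module member is guaranteed
    # three dedicated high-confidence partners (complex members carry their
    # own specific interactors); all other wiring is preferential attachment
    nodes <- module
    deg <- stats::setNames(rep(1, length(module)), module)  # +1 smoothing
    deg[ea] <- deg[ea] + 1; deg[eb] <- deg[eb] + 1
    n_dedicated <- min(3L * length(module), length(rest))
    for (i in seq_along(rest)) {
      v <- rest[i]
      k <- min(config$attach_edges, length(nodes))
      if (i <= n_dedicated) {
        primary <- module[((i - 1L) %% length(module)) + 1L]
        extra <- if (k > 1) sample(setdiff(nodes, primary), k - 1L,
                                   prob = deg[setdiff(nodes, primary)]) else character(0)
        tgt <- c(primary, extra)
      } else {
        tgt <- sample(nodes, k, prob = deg[nodes])
      }
      ea <- c(ea, rep(v, length(tgt))); eb <- c(eb, tgt)
      # the first (strongest-evidence) interaction of a new protein clears
      # the 0.7 confidence cut; further edges follow the low-skewed bulk
      sc <- c(sc, c(stats::runif(1, 0.70, 0.95),
                    stats::runif(length(tgt) - 1, 0.30, 0.90)))
      deg[tgt] <- deg[tgt] + 1
      deg[v] <- 1 + length(tgt)
      nodes <- c(nodes, v)
    }
    edges <- data.frame(node_a = ea, node_b = eb, score = round(sc, 3),
                        stringsAsFactors = FALSE)
    # canonical order, drop any duplicate pair (PA cannot create them, but be safe)
    flip <- edges$node_a > edges$node_b
    tmp <- edges$node_a[flip]
    edges$node_a[flip] <- edges$node_b[flip]
    edges$node_b[flip] <- tmp
    edges <- edges[!duplicated(edges[, 1:2]), ]
    rownames(edges) <- NULL
    list(edges = edges, nodes = nodes, truth = list(module = module))
  })
}

#' Simulate overlapping pathway gene sets
#'
#' Pathways `P01..P09` form a crosstalk cluster: each draws
#' `round(overlap_rate * size)` genes from a shared pool of planted DE genes
#' outside the hub module (so the cluster is both enriched in candidates and
#' densely overlapping, without inflating the pathway membership of
#' non-anchor hub genes), the rest from the background universe. The three designated pathways
#' `P01..P03` additionally contain all anchor genes; anchors appear in no
#' other pathway, making the designated trio the ground-truth crucial
#' pathways. Remaining pathways are background draws.
#'
#' @param config a [synthetic_config()].
#' @param anchor_genes anchor genes; defaults to the planted truth.
#' @return named list of gene-set character vectors with attributes
#'   `universe` and `truth` (`designated`, `cluster`, `pool`).
#' @export
gen_pathways <- function(config, anchor_genes = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- planted_truth(config)
  if (is.null(anchor_genes)) anchor_genes <- truth$anchors
  .with_stream(config$seed, 6L, {
    genes <- truth$genes
    bg <- setdiff(genes, anchor_genes)
    pool_src <- setdiff(truth$de_genes, truth$module)
    pool <- sample(pool_src, min(15L, length(pool_src)))
    sz <- config$pathway_size_range
    ids <- sprintf("P%02d", seq_len(config$n_pathways))
    sets <- vector("list", config$n_pathways)
    names(sets) <- ids
    n_cluster <- length(truth$cluster_pathways)
    n_designated <- length(truth$designated_pathways)
    hub_members <- setdiff(truth$module, anchor_genes)
    for (i in seq_len(config$n_pathways)) {
      size <- sample(seq(sz[1], sz[2]), 1)
      if (i <= n_cluster) {
        n_pool <- min(round(config$overlap_rate * size), length(pool))
        members <- c(sample(pool, n_pool),
                     sample(hub_members, min(2L, length(hub_members))))
        fill <- sample(setdiff(bg, c(members, pool, hub_members)),
                       max(0, size - length(members)))
        members <- c(members, fill)
        if (ids[i] %in% truth$designated_pathways) {
          members <- c(anchor_genes, members)
        } else {
          # each anchor also sits in its own share of the remaining cluster
          # pathways (disjoint across anchors, so the pathways common to all
          # anchors stay exactly the designated trio)
          members <- c(anchor_genes[((i - n_designated - 1) %% length(anchor_genes)) + 1],
                       members)
        }
      } else {
        members <- sample(setdiff(bg, c(pool, hub_members)), size)
      }
      sets[[i]] <- sort(unique(members))
    }
    attr(sets, "universe") <- genes
    attr(sets, "truth") <- list(designated = truth$designated_pathways,
                                cluster = truth$cluster_pathways, pool = pool)
    sets
  })
}

#' Simulate 3'UTR sequences with planted seed sites
#'
#' Positive UTRs (the anchor genes) contain exactly `n_planted_sites`
#' occurrences of the reverse complement of miRNA positions 2-8, each
#' embedded in a 17-nt window whose flanks are drawn from {A, U} so the
#' window AU fraction is at least 0.6. Negative UTRs contain zero
#' occurrences. The first positive UTR additionally carries an overlapping
#' AUUUA pair beside a U-run (class II AU-rich element); the second a lone
#' AUUUA near a U-run (class I); the third a U-run only (class III).
#'
#' @param config a [synthetic_config()].
#' @param mirna miRNA sequence, 5' to 3' (default hsa-miR-106b-5p).
#' @param negatives number of negative UTRs.
#' @return list with `mirna`, `utrs` (named character vector) and `truth`
#'   (data.frame `utr_id`, `start`, `end` of planted sites, 0-based
#'   half-open).
#' @export
gen_sequences <- function(config, mirna = "UAAAGUGCUGACAGUGCAGAU",
                          negatives = 3L) {
  stopifnot(inherits(config, "synthetic_config"))
  mirna <- .as_rna(mirna, "miRNA")
  if (nchar(mirna) < 8) stop("invalid-sequence error: miRNA shorter than 8 nt")
  site <- rna_revcomp(substr(mirna, 2, 8))
  truth <- planted_truth(config)
  .with_stream(config$seed, 7L, {
    L <- config$utr_length
    alphabet <- c("A", "U", "C", "G")
    base_prob <- c(0.28, 0.28, 0.22, 0.22)
    draw_clean <- function() {
      for (i in 1:200) {
        s <- paste(sample(alphabet, L, TRUE, base_prob), collapse = "")
        if (length(.scan_sites(s, site)) == 0L) return(s)
      }
      stop("could not draw a site-free background sequence")
    }
    are_inserts <- list(paste0("AUUUAUUUA", strrep("U", 9)),
                        paste0("AUUUA", "GG", strrep("U", 9)),
                        strrep("U", 12))
    pos_ids <- truth$anchors
    neg_ids <- setdiff(truth$module, truth$anchors)[seq_len(negatives)]
    utrs <- character(0)
    rows <- list()
    for (j in seq_along(pos_ids)) {
      repeat {
        s <- draw_clean()
        # ARE decoration in the first third, seed windows in the rest
        ins <- are_inserts[[((j - 1) %% 3) + 1]]
        substr(s, 10, 9 + nchar(ins)) <- ins
        starts <- integer(0)
        lo <- floor(L / 3)
        cand <- seq(lo, L - 17, by = 25)
        starts0 <- as.integer(sort(sample(cand, config$n_planted_sites)))
        for (st in starts0) {
          flank1 <- paste(sample(c("A", "U"), 5, TRUE), collapse = "")
          flank2 <- paste(sample(c("A", "U"), 5, TRUE), collapse = "")
          substr(s, st + 1, st + 17) <- paste0(flank1, site, flank2)
          starts <- c(starts, st + 5L)  # 0-based site start
        }
        if (identical(.scan_sites(s, site), as.integer(starts))) break
      }
      utrs[pos_ids[j]] <- s
      rows[[length(rows) + 1]] <- data.frame(utr_id = pos_ids[j],
                                             start = starts,
                                             end = starts + 7L)
    }
    for (id in neg_ids) utrs[id] <- draw_clean()
    truth_df <- do.call(rbind, rows)
    rownames(truth_df) <- NULL
    list(mirna = mirna, utrs = utrs, truth = truth_df)
  })
}

# All 0-based offsets where `site` occurs in `s` (overlapping included).
.scan_sites <- function(s, site) {
  w <- nchar(site)
  n <- nchar(s)
  if (n < w) return(integer(0))
  starts <- seq_len(n - w + 1L)
  hits <- substring(s, starts, starts + w - 1L) == site
  as.integer(starts[hits] - 1L)
}

#' Simulate the clinical covariate table
#'
#' One ordinal covariate (lymph-node class) depends on the marker expression
#' through a latent Gaussian with slope `clinical_effect`; every other
#' covariate, and the censored survival time, is independent of expression.
#'
#' @param config a [synthetic_config()].
#' @param marker_expression per-sample marker values; defaults to a
#'   `n_clinical`-sample standard-normal draw (stream-seeded).
#' @return data.frame of covariates with attribute `assoc_types` mapping each
#'   clinical item to its test, plus the marker as attribute `marker`.
#' @export
gen_clinical <- function(config, marker_expression = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_stream(config$seed, 8L, {
    n <- if (is.null(marker_expression)) config$n_clinical else length(marker_expression)
    if (is.null(marker_expression)) marker_expression <- stats::rnorm(n)
    z <- as.numeric(scale(marker_expression))
    latent <- config$clinical_effect * z + stats::rnorm(n)
    lymph <- cut(latent, stats::quantile(latent, c(0, .4, .7, .9, 1)),
                 labels = c("0", "1-3", "4-9", "10+"), include.lowest = TRUE)
    clin <- data.frame(
      lymph_nodes = lymph,
      tumor_purity = stats::runif(n, 0.3, 1),
      race = factor(sample(c("white", "black", "asian"), n, TRUE)),
      pathology_m = factor(sample(c("M0", "M1"), n, TRUE, c(.9, .1))),
      years_to_birth = round(stats::runif(n, 25, 80)),
      histology = factor(sample(c("squamous", "adeno", "adenosquamous"),
                                n, TRUE, c(.7, .2, .1))),
      ethnicity = factor(sample(c("hispanic", "non-hispanic"), n, TRUE, c(.2, .8))),
      radiation = factor(sample(c("yes", "no"), n, TRUE)),
      pathology_n = factor(sample(c("N0", "N1"), n, TRUE, c(.7, .3))),
      pathology_t = factor(sample(c("T1", "T2", "T3", "T4"), n, TRUE)),
      os_time = round(stats::rexp(n, 1 / 30), 1),
      os_status = stats::rbinom(n, 1, 0.6)
    )
    attr(clin, "assoc_types") <- c(
      lymph_nodes = "kruskal_wallis", tumor_purity = "spearman",
      race = "kruskal_wallis", pathology_m = "wilcoxon",
      years_to_birth = "spearman", histology = "kruskal_wallis",
      ethnicity = "wilcoxon", radiation = "wilcoxon",
      pathology_n = "wilcoxon", pathology_t = "kruskal_wallis",
      overall_survival = "cox")
    attr(clin, "marker") <- marker_expression
    clin
  })
}

#' Simulate the cross-cohort validation expression panel
#'
#' Emulates the independent tumor/normal cohorts used to re-test the core
#' genes: in each of `n_validation_studies` studies, only the anchor genes
#' are shifted (by `validation_shift * sigma` on the log2 scale); every other
#' gene in the universe is null. This is the input of the median-rank
#' multi-study meta-analysis, where the anchor signal replicates across
#' cohorts and the remaining core genes do not.
#'
#' @param config a [synthetic_config()].
#' @return list of `expression_study` objects (log2 scale already applied is
#'   FALSE; values raw).
#' @export
gen_validation_studies <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- planted_truth(config)
  .with_stream(config$seed, 9L, {
    lapply(seq_len(config$n_validation_studies), function(i) {
      n <- config$validation_n
      base <- stats::runif(config$n_genes, 4, 12)
      log2_vals <- matrix(stats::rnorm(config$n_genes * 2 * n, base, config$sigma),
                          nrow = config$n_genes,
                          dimnames = list(truth$genes,
                                          sprintf("v%d_%02d", i, seq_len(2 * n))))
      tumor_cols <- n + seq_len(n)
      log2_vals[truth$anchors, tumor_cols] <-
        log2_vals[truth$anchors, tumor_cols] +
        config$validation_shift * config$sigma
      .expression_study(2^log2_vals, rep(c("normal", "tumor"), c(n, n)),
                        log2 = FALSE, study_id = sprintf("cohort_%d", i))
    })
  })
}
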