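#' Generate the full synthetic input bundle in memory
#'
#' Calls every generator with the shared planted truth and returns the
#' pipeline's inputs plus the ground truth needed for recovery checks.
#'
#' @param config a [synthetic_config()].
#' @return list: `studies`, `tumor_normal`, `votes`, `ppi`, `pathways`,
#'   `sequences`, `clinical`, `validation_studies`, `truth`.
#' @export
make_bundle <- function(config) {
  truth <- planted_truth(config)
  tn <- gen_tumor_normal_matrix(config)
  seqs <- gen_sequences(config)
  list(studies = gen_expression_studies(config),
       tumor_normal = tn$study,
       votes = gen_target_votes(config),
       ppi = gen_ppi(config),
       pathways = gen_pathways(config),
       sequences = seqs,
       clinical = gen_clinical(config),
       validation_studies = gen_validation_studies(config),
       truth = c(truth, list(site_offsets = seqs$truth)))
}

#' Write the synthetic bundle as a file fixture set
#'
#' Emits every input in the pipeline's exchange formats: expression TSVs
#' with group files, a STRING-style edge TSV, a GMT, FASTA files for the
#' miRNA and the UTRs, a clinical TSV, and a ground-truth JSON sidecar.
#'
#' @param config a [synthetic_config()].
#' @param outdir writable output directory (created if missing).
#' @return invisibly, the bundle that was written.
#' @export
make_fixtures <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- make_bundle(config)
  for (st in bundle$studies) {
    write_expression_study(st, file.path(outdir, st$study_id))
  }
  write_expression_study(bundle$tumor_normal, file.path(outdir, "tumor_normal"))
  for (st in bundle$validation_studies) {
    write_expression_study(st, file.path(outdir, st$study_id))
  }
  utils::write.table(data.frame(gene = rownames(bundle$votes), bundle$votes),
                     file.path(outdir, "target_votes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_edges(bundle$ppi$edges, file.path(outdir, "ppi_edges.tsv"))
  write_gmt(bundle$pathways, file.path(outdir, "pathways.gmt"))
  write_fasta(stats::setNames(bundle$sequences$mirna, "miR-106b-5p"),
              file.path(outdir, "mirna.fa"))
  write_fasta(bundle$sequences$utrs, file.path(outdir, "utrs.fa"))
  utils::write.table(bundle$clinical, file.path(outdir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(jsonlite::toJSON(list(
    de_genes = bundle$truth$de_genes, anchors = bundle$truth$anchors,
    module = bundle$truth$module, targets = bundle$truth$targets,
    designated_pathways = bundle$truth$designated_pathways,
    site_offsets = bundle$truth$site_offsets), auto_unbox = FALSE)),
    file.path(outdir, "truth.json"))
  invisible(bundle)
}

#' Run the whole cascade end-to-end
#'
#' Executes clinical association, miRNA meta-analysis, candidate screening,
#' pathway enrichment, interaction-network hub voting, pathway crosstalk
#' with MCODE, key-gene meta-analysis with leave-one-out stability, and
#' seed-site scanning, in that order, on a synthetic bundle. The report
#' names the hub genes, main genes, key genes, crucial pathways and seed
#' sites, and carries a reproducibility manifest (seed, config fingerprint,
#' per-stage counts). Identical config implies an identical report.
#'
#' @param config a [synthetic_config()]; alternatively a prebuilt bundle
#'   from [make_bundle()] plus an explicit `seed`.
#' @param bundle optional prebuilt bundle (overrides generation).
#' @param n_perm permutation-null size of the key-gene meta-analysis.
#' @param min_vote,lfc_cut,fdr_cut,min_ppi_score,top_k,min_count,mcode_min_score
#'   stage parameters with the cascade's published defaults.
#' @return object of class `mirkey_report` (a list of per-stage results,
#'   `summary` and `manifest`).
#' @export
run_all <- function(config, bundle = NULL, n_perm = 2000L,
                    min_vote = 5L, lfc_cut = 1, fdr_cut = 0.05,
                    min_ppi_score = 0.7, top_k = 20L, min_count = 2L,
                    mcode_min_score = 4) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(bundle)) bundle <- make_bundle(config)

  # 1. clinical association battery
  clinical <- clinical_assoc(attr(bundle$clinical, "marker"), bundle$clinical)

  # 2. miRNA expression meta-analysis
  effects <- study_effects(bundle$studies)
  het <- heterogeneity(effects)
  model <- select_model(het$p_Q, het$I2)
  pooled <- if (model == "random") pool_random(effects) else pool_fixed(effects)
  meta <- list(effects = effects, heterogeneity = het, model = model,
               pooled = pooled,
               egger = if (nrow(effects) >= 3) egger_test(effects) else NULL,
               influence = if (nrow(effects) >= 3) influence_loo(effects) else NULL,
               sensitivity = sensitivity_switch(effects),
               subgroups = subgroup_pool(effects))

  # 3. candidate screen: DEGs x multi-database votes
  degs <- de_test(bundle$tumor_normal, lfc_cut = lfc_cut, fdr_cut = fdr_cut)
  predicted <- vote_filter(bundle$votes, min_db = min_vote)
  screen <- intersect_candidates(degs, predicted)
  if (length(screen$candidates) == 0) {
    stop("stage 'screen' failed: empty candidate set")
  }

  # 4. pathway enrichment of the candidates
  universe <- rownames(bundle$tumor_normal$values)
  enrich <- hypergeom_enrich(screen$candidates, bundle$pathways, universe)
  sig_pathways <- enrich$term_id[enrich$category == "pathway" & enrich$significant]

  # 5. interaction network: filter, main component, core, hub consensus
  g <- ppi_graph(bundle$ppi$edges)
  g <- igraph::induced_subgraph(
    g, intersect(igraph::V(g)$name, screen$candidates))
  g <- main_component(filter_edges(g, min_score = min_ppi_score))
  core <- main_component(degree_betweenness_core(g))
  cent <- centralities(core, epc_seed = config$seed)
  hubs <- consensus_hubs(cent, top_k = top_k, min_count = min_count)
  hub_genes <- hubs$gene[hubs$hub]

  # 6. pathway crosstalk, MCODE, bipartite gene-pathway core
  ct <- build_crosstalk(bundle$pathways[sig_pathways])
  clusters <- mcode(ct, min_score = mcode_min_score)
  member_sets <- attr(clusters, "member_sets")
  cluster_pathways <- unique(unlist(member_sets[clusters$retained]))
  gp <- map_gene_pathway(hub_genes, bundle$pathways[cluster_pathways])
  core_sel <- select_core(gp)
  main_genes <- core_sel$genes

  # 7. key genes: median-rank multi-study meta with LOO stability
  pv <- gene_study_pvals(bundle$validation_studies)
  keytab <- keygene_influence(pv, genes_of_interest = main_genes,
                              n_perm = n_perm, seed = config$seed)
  key_genes <- keytab$gene[keytab$key]
  crucial <- if (length(key_genes)) crucial_pathways(key_genes, gp) else character(0)

  # 8. seed sites and ARE classes on the UTRs
  sites <- seed_sites_all(bundle$sequences$mirna, bundle$sequences$utrs)
  ares <- lapply(names(bundle$sequences$utrs), function(id) {
    classify_are(bundle$sequences$utrs[[id]], utr_id = id)
  })

  cfg_json <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
  manifest <- list(seed = config$seed, config = unclass(config),
                   config_hash = .fnv1a(cfg_json),
                   package_version = as.character(utils::packageVersion("mirkey")),
                   counts = list(n_deg = sum(degs$selected),
                                 n_predicted = length(predicted),
                                 n_candidates = length(screen$candidates),
                                 n_sig_pathways = length(sig_pathways),
                                 core_nodes = igraph::vcount(core),
                                 n_hubs = length(hub_genes),
                                 n_cluster_pathways = length(cluster_pathways),
                                 n_main_genes = length(main_genes),
                                 n_key_genes = length(key_genes),
                                 n_seed_sites = nrow(sites)))

  structure(list(clinical = clinical, meta = meta, degs = degs,
                 screen = screen, enrichment = enrich, centralities = cent,
                 hubs = hubs, crosstalk = ct, clusters = clusters,
                 gene_pathway = gp, keygenes = keytab,
                 seed_sites = sites, are_reports = ares,
                 summary = list(hub_genes = sort(hub_genes),
                                main_genes = main_genes,
                                key_genes = sort(key_genes),
                                crucial_pathways = crucial,
                                pooled_smd = pooled$pooled,
                                model = model),
                 manifest = manifest),
            class = "mirkey_report")
}

#' @export
print.mirkey_report <- function(x, ...) {
  s <- x$summary
  cat("<mirkey_report>\n")
  cat(sprintf("  pooled SMD (%s model): %.3f\n", s$model, s$pooled_smd))
  cat(sprintf("  candidates: %d; hub genes: %d; main genes: %d\n",
              x$manifest$counts$n_candidates, length(s$hub_genes),
              length(s$main_genes)))
  cat(sprintf("  key genes: %s\n", paste(s$key_genes, collapse = ", ")))
  cat(sprintf("  crucial pathways: %s\n", paste(s$crucial_pathways, collapse = ", ")))
  cat(sprintf("  seed sites found: %d\n", nrow(x$seed_sites)))
  invisible(x)
}
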