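#' Default pipeline configuration
#'
#' Builds the nested run configuration with the analysis thresholds used
#' throughout: adjusted p < 0.05 and |log2FC| > 1 for DE selection,
#' geneset sizes 10-500 with Bonferroni control at 0.05, top-50 lists at
#' raw p < 0.01. Any element can be overridden via `...` (named nested
#' lists are merged).
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory.
#' @param stages which stages to run, in fixed order; subset of
#'   `c("simulate", "de", "enrich", "panels", "timelapse", "qpcr")`.
#' @param ... overrides, e.g. `sim = list(n_genes = 2000)`.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = "tuftdyn_run",
                               stages = c("simulate", "de", "enrich",
                                          "panels", "timelapse", "qpcr"),
                               ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir, stages = stages,
    thresholds = list(padj_max = 0.05, lfc_min = 1, min_size = 10,
                      max_size = 500, alpha = 0.05, top_k = 50,
                      p_max = 0.01),
    sim = list(n_mice = 5, n_genes = 5000, library_size_mean = 5e5,
               mouse_sd = 0.15, dispersion = 0.05, n_de_genes = 300,
               de_lfc = 2),
    genesets = list(n_sets = 200, size_range = c(10, 500), n_planted = 5),
    tracks = list(n_cells = 119),
    compartment = list(n_animals = 3, per_region_cells = 350,
                       p_double_villus = 0.98, p_double_crypt = 0.46),
    qpcr = list(n_genes = 379, n_enriched = 1, fold = 1000),
    inputs = list()   # external input paths when the simulate stage is off
  )
  ov <- list(...)
  merge_cfg <- function(base, over) {
    # apply positionally so repeated names are merged in call order
    for (i in seq_along(over)) {
      nm <- names(over)[i]
      if (is.list(base[[nm]]) && is.list(over[[i]])) {
        base[[nm]] <- merge_cfg(base[[nm]], over[[i]])
      } else {
        base[[nm]] <- over[[i]]
      }
    }
    base
  }
  structure(merge_cfg(cfg, ov), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [default_run_config()]
#'   fields.
#' @return `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  do.call(default_run_config, yaml::read_yaml(path))
}

stage_seed <- function(cfg, k) (cfg$seed * 131L + k) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order — simulate, differential
#' expression (all three pairwise population contrasts), geneset
#' enrichment, marker panels, time-lapse quantification, qPCR — writing
#' every table under `out_dir` and a machine-readable `manifest.json`
#' recording seeds, per-stage row counts and an md5 checksum for every
#' output file. Reruns with the same config are byte-identical for all
#' table outputs.
#'
#' @param cfg a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- cfg$stages
  known <- c("simulate", "de", "enrich", "panels", "timelapse", "qpcr")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  # validate inputs before any stage runs
  if (!"simulate" %in% stages) {
    need <- c(if (any(c("de", "enrich", "panels") %in% stages))
                c("counts", "meta"),
              if ("enrich" %in% stages) "gmt",
              if ("timelapse" %in% stages) c("tracks", "compartment"),
              if ("qpcr" %in% stages) "ct")
    need <- unique(need)
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss) > 0) {
      stop("simulate stage disabled but inputs missing: ",
           paste(miss, collapse = ", "))
    }
    paths <- unlist(cfg$inputs[need])
    if (!all(file.exists(paths))) {
      stop("input file(s) not found: ",
           paste(paths[!file.exists(paths)], collapse = ", "))
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("tuftdyn")),
                   seed = cfg$seed, stages = stages, rows = list(),
                   skipped = setdiff(known, stages))
  th <- cfg$thresholds

  # --- simulate ------------------------------------------------------------
  sim <- NULL; genesets <- NULL; trk <- NULL; comp <- NULL; ct <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_counts(do.call(sim_config,
                                   c(cfg$sim, seed = stage_seed(cfg, 1L))))
    write_counts_tsv(sim$cm, pth("counts.tsv"), pth("sample_meta.tsv"))
    write_tsv(sim$truth, pth("truth_genes.tsv"))
    de_genes <- sim$truth$gene_id[sim$truth$planted]
    genesets <- simulate_genesets(sim$truth$gene_id,
                                  n_sets = cfg$genesets$n_sets,
                                  size_range = cfg$genesets$size_range,
                                  n_planted = cfg$genesets$n_planted,
                                  de_genes = de_genes,
                                  seed = stage_seed(cfg, 2L))
    write_gmt(genesets$sets, pth("genesets.gmt"))
    trk <- simulate_tracks(do.call(track_sim_config,
                                   c(cfg$tracks, seed = stage_seed(cfg, 3L))))
    write_csv(trk$tracks, pth("tracks.csv"))
    write_csv(trk$truth, pth("truth_tracks.csv"))
    comp <- do.call(simulate_compartment_counts,
                    c(cfg$compartment, seed = stage_seed(cfg, 4L)))
    write_csv(comp, pth("compartment_counts.csv"))
    qp <- cfg$qpcr
    ct <- simulate_ct(n_genes = qp$n_genes,
                      enriched_ids = sprintf("gpcr%03d", seq_len(qp$n_enriched)),
                      fold = qp$fold, seed = stage_seed(cfg, 5L))
    write_csv(ct, pth("ct_table.csv"))
    manifest$rows$simulate <- list(genes = nrow(sim$cm$counts),
                                   samples = ncol(sim$cm$counts),
                                   genesets = length(genesets$sets),
                                   cells = nrow(trk$truth))
  } else {
    if (any(c("de", "enrich", "panels") %in% stages)) {
      sim <- list(cm = read_counts_tsv(cfg$inputs$counts, cfg$inputs$meta))
    }
    if ("enrich" %in% stages) genesets <- list(sets = read_gmt(cfg$inputs$gmt))
    if ("timelapse" %in% stages) {
      trk <- list(tracks = read_tracks_csv(cfg$inputs$tracks))
      comp <- utils::read.csv(cfg$inputs$compartment, stringsAsFactors = FALSE)
    }
    if ("qpcr" %in% stages) ct <- read_ct_csv(cfg$inputs$ct)
  }

  # --- differential expression --------------------------------------------
  de_main <- NULL; sf <- NULL
  if (any(c("de", "enrich", "panels") %in% stages)) {
    sf <- size_factors(sim$cm)
    disp <- estimate_dispersion(sim$cm, sf)
    contrasts <- list(c("mature_tuft", "young_tuft"),
                      c("young_tuft", "background"),
                      c("mature_tuft", "background"))
    if ("de" %in% stages) {
      for (ctr in contrasts) {
        de <- fit_paired_nb_wald(sim$cm, sf, disp, contrast = ctr)
        write_tsv(de[, c("gene_id", "base_mean", "log2fc", "se", "wald_stat",
                         "p", "padj")],
                  pth(sprintf("de_%s_vs_%s.tsv", ctr[1], ctr[2])))
        if (identical(ctr, contrasts[[1]])) de_main <- de
      }
      sel <- select_de(de_main, th$padj_max, th$lfc_min)
      write_tsv(sel[, c("gene_id", "log2fc", "padj")], pth("de_selected.tsv"))
      manifest$rows$de <- list(tested = nrow(de_main), selected = nrow(sel))
    } else {
      de_main <- fit_paired_nb_wald(sim$cm, sf, disp,
                                    contrast = contrasts[[1]])
    }
  }

  # --- enrichment ----------------------------------------------------------
  if ("enrich" %in% stages) {
    sc <- signed_scores(de_main)
    enr <- enrich_collection(sc, genesets$sets, min_size = th$min_size,
                             max_size = th$max_size, alpha = th$alpha)
    write_tsv(enr[, c("set_name", "n_in", "u_stat", "z", "p_enrich",
                      "bonferroni_significant", "x_volcano", "y_volcano")],
              pth("enrichment.tsv"))
    manifest$rows$enrich <- list(tested = nrow(enr),
                                 significant = sum(enr$bonferroni_significant))
  }

  # --- marker panels -------------------------------------------------------
  if ("panels" %in% stages) {
    up <- suppressWarnings(top_k_by_lfc(de_main, th$top_k, "up", th$p_max))
    dn <- suppressWarnings(top_k_by_lfc(de_main, th$top_k, "down", th$p_max))
    write_tsv(up[, c("gene_id", "log2fc", "p")], pth("top_up.tsv"))
    write_tsv(dn[, c("gene_id", "log2fc", "p")], pth("top_down.tsv"))
    panel <- log2p1_panel(sim$cm, sf, c(dn$gene_id, up$gene_id))
    write_tsv(data.frame(gene_id = rownames(panel), panel,
                         check.names = FALSE), pth("panel_log2p1.tsv"))
    manifest$rows$panels <- list(up = nrow(up), down = nrow(dn))
  }

  # --- time-lapse ----------------------------------------------------------
  if ("timelapse" %in% stages) {
    cls <- classify_tracks(trk$tracks)
    write_csv(cls, pth("track_classification.csv"))
    lg <- summarize_lags(cls)
    write_tsv(data.frame(mean_lag_h = lg$mean_h, sem_h = lg$sem_h, n = lg$n),
              pth("lag_summary.tsv"))
    cf <- colocalization_fractions(comp)
    write_tsv(cf$summary, pth("colocalization.tsv"))
    manifest$rows$timelapse <- list(cells = nrow(cls),
                                    transitions = lg$n)
  }

  # --- qPCR ----------------------------------------------------------------
  if ("qpcr" %in% stages) {
    rel <- ddct_relative_expression(ct)
    scat <- enrichment_scatter_table(rel, label_top = 5)
    write_tsv(scat, pth("qpcr_scatter.tsv"))
    manifest$rows$qpcr <- list(genes = nrow(rel))
  }

  # --- manifest ------------------------------------------------------------
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  writeLines(cfg_yaml, pth("config.yaml"))
  files <- setdiff(list.files(cfg$out_dir), "manifest.json")
  manifest$config_md5 <- unname(tools::md5sum(pth("config.yaml")))
  manifest$files <- lapply(stats::setNames(files, files), function(f) {
    list(md5 = unname(tools::md5sum(pth(f))), bytes = file.size(pth(f)))
  })
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
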