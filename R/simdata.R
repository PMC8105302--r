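#' Configuration for the synthetic paired count simulator
#'
#' Defaults emulate the study design: five mice, each contributing one
#' sorted library per population (background, young and mature tuft cells),
#' negative-binomial counts with log-additive mouse effects, and a block of
#' genes carrying a planted log2 fold change in mature vs young tuft cells.
#'
#' @param n_mice number of mice (paired libraries per population); >= 2.
#' @param n_genes number of genes.
#' @param library_size_mean expected total counts per library; individual
#'   library sizes are log-normal around this value (cv ~ 20%).
#' @param mouse_sd SD of per-mouse log-scale effects (natural log).
#' @param dispersion NB dispersion alpha, Var = mu + alpha * mu^2.
#' @param n_de_genes number of genes with a planted mature-vs-young effect
#'   (the first `n_de_genes` genes).
#' @param de_lfc planted log2 fold change (mature_tuft vs young_tuft);
#'   scalar or vector recycled over the planted genes, signed.
#' @param seed integer seed; all randomness derives from it.
#'
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_mice = 5, n_genes = 22189, library_size_mean = 2e6,
                       mouse_sd = 0.15, dispersion = 0.05,
                       n_de_genes = 1000, de_lfc = 2, seed = 1L) {
  if (n_mice < 2) stop("n_mice must be >= 2")
  if (n_genes < 1 || library_size_mean <= 0) stop("invalid config: nonpositive dimensions")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (mouse_sd < 0) stop("mouse_sd must be >= 0")
  if (n_de_genes < 0 || n_de_genes > n_genes) stop("n_de_genes out of range")
  structure(list(n_mice = as.integer(n_mice), n_genes = as.integer(n_genes),
                 populations = tuft_populations(),
                 library_size_mean = library_size_mean, mouse_sd = mouse_sd,
                 dispersion = dispersion, n_de_genes = as.integer(n_de_genes),
                 de_lfc = de_lfc, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a paired three-population count matrix with planted effects
#'
#' Counts are drawn NB(mu, alpha) with
#' log mu = gene baseline + log library size + mouse effect + population
#' effect; the first `n_de_genes` genes carry the planted mature-vs-young
#' log2 fold change (applied to the mature population, centred so young
#' stays at baseline). Ground truth is returned alongside.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `cm` (a [count_matrix()]) and `truth`
#'   (data.frame: gene_id, planted logical, true_log2fc mature vs young).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
    pops <- cfg$populations
    meta <- expand.grid(mouse = sprintf("m%d", seq_len(cfg$n_mice)),
                        population = pops, stringsAsFactors = FALSE)
    meta <- meta[order(meta$mouse, match(meta$population, pops)), ]
    meta$sample <- sprintf("%s_%s", meta$mouse, meta$population)
    meta <- meta[, c("sample", "mouse", "population")]
    n_samp <- nrow(meta)

    # gene baselines: log-normal abundances summing roughly to the library
    base_abund <- exp(stats::rnorm(cfg$n_genes, mean = 0, sd = 1.8))
    base_frac <- base_abund / sum(base_abund)
    lib <- cfg$library_size_mean *
      exp(stats::rnorm(n_samp, -0.02, 0.2))  # ~20% cv, mean-preserving-ish
    # gene-specific per-mouse effects: shared across the mouse's three
    # libraries, hence removable by the pairing factor (a purely
    # sample-level effect would be absorbed by size factors instead)
    mouse_eff <- matrix(stats::rnorm(cfg$n_genes * cfg$n_mice, 0,
                                     cfg$mouse_sd),
                        cfg$n_genes, cfg$n_mice,
                        dimnames = list(NULL,
                                        sprintf("m%d", seq_len(cfg$n_mice))))

    true_l2fc <- numeric(cfg$n_genes)
    if (cfg$n_de_genes > 0) {
      true_l2fc[seq_len(cfg$n_de_genes)] <-
        rep_len(cfg$de_lfc, cfg$n_de_genes)
    }
    # mature gets the planted effect; young and background stay at baseline
    pop_l2fc <- matrix(0, cfg$n_genes, length(pops),
                       dimnames = list(genes, pops))
    pop_l2fc[, "mature_tuft"] <- true_l2fc

    mu <- matrix(0, cfg$n_genes, n_samp)
    for (j in seq_len(n_samp)) {
      mu[, j] <- base_frac * lib[j] *
        exp(mouse_eff[, meta$mouse[j]]) *
        2^pop_l2fc[, meta$population[j]]
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$dispersion),
                     nrow = cfg$n_genes,
                     dimnames = list(genes, meta$sample))
    cm <- count_matrix(counts, meta)
    truth <- data.frame(gene_id = genes,
                        planted = seq_len(cfg$n_genes) <= cfg$n_de_genes,
                        true_log2fc = true_l2fc,
                        stringsAsFactors = FALSE)
    list(cm = cm, truth = truth)
  })
}

#' Simulate a geneset collection with planted enriched sets
#'
#' Null sets are sampled uniformly without replacement from the universe;
#' planted sets are drawn preferentially from `de_genes` (filled with random
#' genes only when `de_genes` is too small), so downstream enrichment is
#' detectable.
#'
#' @param universe character vector of gene ids.
#' @param n_sets total number of sets.
#' @param size_range integer pair, inclusive bounds on set size.
#' @param n_planted number of planted (DE-loaded) sets; must be <= n_sets.
#' @param de_genes gene ids carrying planted effects (required if
#'   `n_planted > 0`).
#' @param seed integer seed.
#' @return list: `sets` (named list of id vectors), `planted` (set names).
#' @export
simulate_genesets <- function(universe, n_sets, size_range = c(10, 500),
                              n_planted = 0, de_genes = character(),
                              seed = 1L) {
  if (size_range[1] < 2 || size_range[2] > length(universe)) {
    stop("size_range must lie within [2, length(universe)]")
  }
  if (n_planted > n_sets) stop("n_planted > n_sets")
  if (n_planted > 0 && length(de_genes) == 0) {
    stop("planted sets need de_genes")
  }
  withr::with_seed(seed, {
    sizes <- size_range[1] +
      sample.int(size_range[2] - size_range[1] + 1, n_sets,
                 replace = TRUE) - 1L
    nm <- sprintf("set%04d", seq_len(n_sets))
    planted_idx <- seq_len(n_planted)
    sets <- lapply(seq_len(n_sets), function(i) {
      s <- sizes[i]
      if (i %in% planted_idx) {
        k <- min(s, length(de_genes))
        mem <- sample(de_genes, k)
        if (k < s) {
          mem <- c(mem, sample(setdiff(universe, mem), s - k))
        }
        mem
      } else {
        sample(universe, s)
      }
    })
    names(sets) <- nm
    list(sets = sets, planted = nm[planted_idx])
  })
}

#' Configuration for the time-lapse track simulator
#'
#' Defaults emulate the organoid cohort: 119 fluorescent cells imaged every
#' 3 h for 60 h, with category fractions matching the observed tallies
#' (58 transitioning, 33 GFP-only, 25 double-positive at start, 3
#' mCherry-only) and a GFP-to-mCherry onset lag centred at 10.8 h.
#'
#' @param n_cells number of tracked cells.
#' @param frame_interval_h hours between frames.
#' @param horizon_h total imaging horizon in hours.
#' @param lag_mean_h,lag_sd_h mean/SD (hours) of the parent normal of the
#'   0-truncated lag distribution.
#' @param fraction_transitioning,fraction_gfp_only,fraction_both_at_start,fraction_mcherry_only
#'   category probabilities; must sum to 1.
#' @param seed integer seed.
#' @return list of class `track_sim_config`.
#' @export
track_sim_config <- function(n_cells = 119, frame_interval_h = 3,
                             horizon_h = 60, lag_mean_h = 10.8,
                             lag_sd_h = 4,
                             fraction_transitioning = 58 / 119,
                             fraction_gfp_only = 33 / 119,
                             fraction_both_at_start = 25 / 119,
                             fraction_mcherry_only = 3 / 119,
                             seed = 1L) {
  fr <- c(fraction_transitioning, fraction_gfp_only,
          fraction_both_at_start, fraction_mcherry_only)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9) {
    stop("category fractions must lie in [0,1] and sum to 1")
  }
  if (horizon_h < frame_interval_h) stop("horizon_h must be >= frame_interval_h")
  if (n_cells < 1 || frame_interval_h <= 0) stop("invalid track config")
  if (lag_mean_h <= 0 || lag_sd_h < 0) stop("invalid lag distribution")
  structure(list(n_cells = as.integer(n_cells),
                 frame_interval_h = frame_interval_h, horizon_h = horizon_h,
                 lag_mean_h = lag_mean_h, lag_sd_h = lag_sd_h,
                 fractions = stats::setNames(fr, c("transition", "GFP_only",
                                                   "both_throughout",
                                                   "mCherry_only")),
                 seed = as.integer(seed)),
            class = "track_sim_config")
}

# normal truncated to [0, upper]; inverse-CDF sampling
rtruncnorm01 <- function(n, mean, sd, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, 0), upper), n))
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate dual-reporter time-lapse tracks
#'
#' Each cell is assigned a category by the configured fractions.
#' Transitioning cells get a continuous GFP onset uniform on
#' `[0, horizon - lag]` with mCherry onset = GFP onset + lag
#' (lag 0-truncated normal); onsets are then discretized to the frame grid:
#' a reporter is observed "on" at the first frame at or after its onset.
#'
#' @param cfg a [track_sim_config()].
#' @return list with `tracks` (data.frame: cell_id, organoid_id, time_h,
#'   gfp, mcherry — one row per cell per frame) and `truth` (data.frame:
#'   cell_id, category, true_gfp_onset_h, true_mcherry_onset_h, true_lag_h).
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "track_sim_config"))
  withr::with_seed(cfg$seed, {
    frames <- seq(0, cfg$horizon_h, by = cfg$frame_interval_h)
    cats <- sample(names(cfg$fractions), cfg$n_cells, replace = TRUE,
                   prob = cfg$fractions)
    n <- cfg$n_cells
    lag <- rep(NA_real_, n)
    on_g <- rep(NA_real_, n)   # continuous GFP onset
    on_m <- rep(NA_real_, n)   # continuous mCherry onset
    tr <- cats == "transition"
    lag[tr] <- rtruncnorm01(sum(tr), cfg$lag_mean_h, cfg$lag_sd_h,
                            upper = cfg$horizon_h)
    on_g[tr] <- stats::runif(sum(tr), 0, cfg$horizon_h - lag[tr])
    on_m[tr] <- on_g[tr] + lag[tr]
    go <- cats == "GFP_only"
    on_g[go] <- stats::runif(sum(go), 0, cfg$horizon_h)
    bo <- cats == "both_throughout"
    on_g[bo] <- 0
    on_m[bo] <- 0
    mo <- cats == "mCherry_only"
    on_m[mo] <- stats::runif(sum(mo), 0, cfg$horizon_h)

    cell_id <- sprintf("cell%04d", seq_len(n))
    organoid_id <- sprintf("org%03d", ceiling(seq_len(n) / 3))
    tracks <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(cell_id = cell_id[i], organoid_id = organoid_id[i],
                 time_h = frames,
                 gfp = as.integer(!is.na(on_g[i]) & frames >= on_g[i]),
                 mcherry = as.integer(!is.na(on_m[i]) & frames >= on_m[i]),
                 stringsAsFactors = FALSE)
    }))
    truth <- data.frame(cell_id = cell_id, category = cats,
                        true_gfp_onset_h = on_g, true_mcherry_onset_h = on_m,
                        true_lag_h = lag, stringsAsFactors = FALSE)
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate crypt/villus co-localization counts
#'
#' Per animal and region, `per_region_cells` detected fluorescent cells are
#' split into double-positive vs single-positive by a binomial draw; the
#' single-positive remainder is split GFP-only vs mCherry-only.
#'
#' @param n_animals number of animals.
#' @param per_region_cells counted cells per animal and region (>= 1;
#'   study design used > 300).
#' @param p_double_villus,p_double_crypt probability a detected cell is
#'   double-positive in each region.
#' @param p_mcherry_only probability a single-positive cell is
#'   mCherry-only (rest are GFP-only).
#' @param seed integer seed.
#' @return data.frame: animal_id, region, n_double, n_gfp_only,
#'   n_mcherry_only, n_total_cells.
#' @export
simulate_compartment_counts <- function(n_animals = 3, per_region_cells = 350,
                                        p_double_villus = 0.98,
                                        p_double_crypt = 0.46,
                                        p_mcherry_only = 0, seed = 1L) {
  p <- c(villus = p_double_villus, crypt = p_double_crypt, p_mcherry_only)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0,1]")
  if (per_region_cells < 1) stop("per_region_cells must be >= 1")
  withr::with_seed(seed, {
    grid <- expand.grid(animal_id = sprintf("animal%d", seq_len(n_animals)),
                        region = c("crypt", "villus"),
                        stringsAsFactors = FALSE)
    pd <- ifelse(grid$region == "villus", p_double_villus, p_double_crypt)
    n_double <- stats::rbinom(nrow(grid), per_region_cells, pd)
    n_single <- per_region_cells - n_double
    n_mch <- stats::rbinom(nrow(grid), n_single, p_mcherry_only)
    data.frame(grid,
               n_double = n_double,
               n_gfp_only = n_single - n_mch,
               n_mcherry_only = n_mch,
               n_total_cells = per_region_cells,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a qPCR Ct table for a receptor array
#'
#' Housekeeping Ct is constant; enriched genes have their
#' target-population Ct lowered by `log2(fold)` cycles relative to the
#' reference population (classic amplification efficiency of 2), with
#' Gaussian Ct measurement noise.
#'
#' @param n_genes number of target genes (array size; study used 379).
#' @param enriched_ids gene ids (subset of `gene%03d` names or custom via
#'   `gene_ids`) enriched in the positive population.
#' @param fold fold enrichment for the enriched genes (> 0).
#' @param ct_noise_sd SD (cycles) of the measurement noise.
#' @param gene_ids optional custom gene ids (length `n_genes`).
#' @param seed integer seed.
#' @return data.frame of class `ct_table`: gene_id, ct_target_pos,
#'   ct_target_neg, ct_housekeeping_pos, ct_housekeeping_neg, detected.
#' @export
simulate_ct <- function(n_genes = 379, enriched_ids = character(),
                        fold = 1000, ct_noise_sd = 0.2,
                        gene_ids = NULL, seed = 1L) {
  if (fold <= 0) stop("fold must be > 0")
  withr::with_seed(seed, {
    if (is.null(gene_ids)) gene_ids <- sprintf("gpcr%03d", seq_len(n_genes))
    stopifnot(length(gene_ids) == n_genes)
    base_ct <- stats::rnorm(n_genes, 30, 1.5)
    hk <- 18
    enr <- gene_ids %in% enriched_ids
    noise <- function() stats::rnorm(n_genes, 0, ct_noise_sd)
    data.frame(gene_id = gene_ids,
               ct_target_pos = base_ct - ifelse(enr, log2(fold), 0) + noise(),
               ct_target_neg = base_ct + noise(),
               ct_housekeeping_pos = hk,
               ct_housekeeping_neg = hk,
               detected = TRUE,
               stringsAsFactors = FALSE)
  })
}
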