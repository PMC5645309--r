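#' Default run configuration
#'
#' The effective configuration of a pipeline run: scenario parameters for
#' the synthetic generator, demultiplexing thresholds, profile window,
#' caller parameters and enhancer-annotation parameters. Every numeric
#' default is the pipeline's standard setting (w = 3, iterations = 1000,
#' fdr = 0.01, fdr_prob = 0.05, k = 9, min_tfs = 6, max_dist = 2000,
#' len_min = 30, qual_min = 20).
#'
#' @param out_dir Output directory of the run.
#' @param seed Master seed.
#' @return A nested list of class \code{"run_config"}.
#' @export
default_run_config <- function(out_dir = "fourcmap_run", seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    scenario = list(n_reads = 20000L, gamma = 20),
    demux = list(qual_min = 20, len_min = 30),
    profile = list(k = 9),
    caller = list(w = 3, iterations = 1000L, fdr = 0.01, fdr_prob = 0.05),
    enhancers = list(min_tfs = 6, max_dist = 2000)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values in the file override the defaults of [default_run_config()];
#' unknown keys are an error.
#'
#' @param path YAML file.
#' @return A \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (k in names(user)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    if (is.list(cfg[[k]])) {
      for (k2 in names(user[[k]])) {
        if (!k2 %in% names(cfg[[k]]))
          stop("unknown config key: ", k, ".", k2)
        cfg[[k]][[k2]] <- user[[k]][[k2]]
      }
    } else cfg[[k]] <- user[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full 4C analysis of a synthetic scenario in memory
#'
#' Executes, for each library of the scenario: simulation, bait
#' demultiplexing, trimming, exact alignment, per-fragment counting and the
#' three artefact filters (replicates are filtered against the control
#' library); then RPM-normalised windowed profiles, per-region
#' permutation-FDR interaction calling for both replicates, replicate
#' overlap, domain counts, gene overlap and enhancer-candidate annotation.
#'
#' @param scn A scenario from [standard_scenario()].
#' @param qual_min,len_min Trimming thresholds.
#' @param k Profile window size in fragments.
#' @param min_tfs,max_dist Enhancer-annotation parameters.
#' @return A list with per-stage results (see the fields of the returned
#'   object); the input scenario is carried as \code{$scenario}.
#' @export
analyse_scenario <- function(scn, qual_min = 20, len_min = 30, k = 9,
                             min_tfs = 6, max_dist = 2000) {
  toy <- scn$toy; bait <- scn$bait
  libs <- names(scn$lib_specs)
  sims <- list(); counts_raw <- list(); demux_tallies <- list()
  for (lib in libs) {
    sim <- simulate_4c_library(toy, bait, scn$model, scn$lib_specs[[lib]],
                               label = lib)
    dm <- demultiplex(sim$pairs, list(bait))
    tr <- trim_and_filter(dm$assigned[[bait$name]], bait,
                          qual_min = qual_min, len_min = len_min)
    loci <- align_exact(tr$reads$seq, toy$genome)
    counts_raw[[lib]] <- count_per_fragment(loci, toy$map, bait$name, lib)
    sims[[lib]] <- sim$truth
    demux_tallies[[lib]] <- dm$tally
  }
  counts <- list(
    rep1 = apply_filters(counts_raw$rep1, bait, counts_raw$control),
    rep2 = apply_filters(counts_raw$rep2, bait, counts_raw$control),
    control = counts_raw$control)

  profiles <- lapply(counts[c("rep1", "rep2")], function(cc)
    running_window_sum(rpm_normalize(cc), k = k))
  cumulative <- cumulative_distance_curve(counts$rep1, bait)

  params2 <- scn$params; params2$seed <- scn$params$seed + 17L
  excl <- if (is.null(scn$exclude_bp)) 0 else scn$exclude_bp
  calls <- list(rep1 = call_bait(counts$rep1, bait, scn$regions, scn$params,
                                 exclude_bp = excl),
                rep2 = call_bait(counts$rep2, bait, scn$regions, params2,
                                 exclude_bp = excl))

  reproducible <- lapply(names(scn$regions), function(rg)
    intersect_replicates(calls$rep1$intervals[[rg]],
                         calls$rep2$intervals[[rg]]))
  names(reproducible) <- names(scn$regions)

  pooled <- unique(do.call(rbind, reproducible))
  domain_counts <- count_domain(pooled, toy$domain)
  genes_hit <- gene_overlap(pooled, toy$genes)

  clusters <- find_tf_clusters(toy$tracks$tf, min_tfs = min_tfs)
  enh <- call_enhancer_candidates(clusters,
                                  stats::setNames(list(pooled), bait$name),
                                  max_dist = max_dist)
  cand <- enh$candidates
  if (nrow(cand)) {
    cand$name <- name_by_tss_distance((cand$start + cand$end) %/% 2,
                                      toy$tss[["P1"]], "+")
    cand$rad21_no_ctcf <- cohesin_ctcf_status(cand, toy$tracks$rad21,
                                              toy$tracks$ctcf)
    cand$cne_overlap <- cne_overlap(cand, toy$tracks$cne)
  }
  list(scenario = scn, truth = sims, demux = demux_tallies,
       counts_raw = counts_raw, counts = counts, profiles = profiles,
       cumulative = cumulative, calls = calls, reproducible = reproducible,
       pooled = pooled, domain_counts = domain_counts, genes_hit = genes_hit,
       clusters = clusters, candidates = cand, supports = enh$supports)
}

#' Planted-enhancer recovery of an analysed scenario
#'
#' Fraction of the scenario's planted fragments that lie inside a
#' replicate-reproducible (category 1/2 in both replicates) significant
#' interval, pooled over regions.
#'
#' @param res Result of [analyse_scenario()].
#' @return List: \code{$recovered}, \code{$n_planted}, \code{$fraction}.
#' @export
planted_recovery <- function(res) {
  fr <- res$scenario$toy$map$fragments
  rows <- res$scenario$toy$truth$planted_rows
  iv <- res$pooled
  hit <- vapply(rows, function(r) {
    any(iv$chrom == fr$chrom[r] & iv$start < fr$end[r] & iv$end > fr$start[r])
  }, logical(1))
  list(recovered = sum(hit), n_planted = length(rows),
       fraction = mean(hit))
}

#' Run the pipeline end-to-end and write all artefacts
#'
#' Executes simulate, demux, quantify, profile, call, overlap and enhancers
#' on the configured synthetic scenario and writes every stage's artefacts
#' under \code{config$out_dir}, together with the effective configuration
#' and a manifest listing every artefact with its MD5 checksum and the
#' seeds used. If the run directory already holds a complete set of
#' artefacts newer than the written config, the run is skipped (all stages
#' marked skipped in the manifest) unless \code{force = TRUE}. A stage
#' failure aborts with the failing stage named; that stage's partial
#' outputs are renamed \code{*.partial}.
#'
#' @param config A \code{"run_config"} (or path to a YAML config).
#' @param force Recompute even if artefacts are fresh.
#' @return The manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config = default_run_config(), force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "config.yaml")

  stage_outputs <- list(
    simulate = c("tracks/genome.fa", "tracks/fragments.bed", "tracks/truth.tsv",
                 as.vector(outer(c("rep1", "rep2", "control"), 1:2,
                                 function(l, m) sprintf("reads_%s_%d.fastq", l, m)))),
    demux = "demux_report.tsv",
    quantify = c("counts_rep1.tsv", "counts_rep2.tsv", "counts_control.tsv",
                 "filter_report.tsv"),
    profile = c("profile_rep1.bedgraph", "profile_rep2.bedgraph",
                "cumulative_rep1.tsv"),
    call = c("calls_rep1.tsv", "calls_rep2.tsv"),
    overlap = c("reproducible.bed", "domain_counts.tsv"),
    enhancers = "candidates.tsv")
  all_outputs <- file.path(out, unlist(stage_outputs, use.names = FALSE))

  fresh <- file.exists(cfg_path) && all(file.exists(all_outputs)) &&
    all(file.mtime(all_outputs) >= file.mtime(cfg_path))
  if (fresh && !force) {
    manifest <- build_manifest(config, stage_outputs, out, skipped = TRUE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(manifest))
  }

  yaml::write_yaml(config[setdiff(names(config), "out_dir")], cfg_path)
  scn <- standard_scenario(seed = config$seed,
                           n_reads = config$scenario$n_reads,
                           gamma = config$scenario$gamma)
  scn$params <- caller_params(w = config$caller$w,
                              iterations = config$caller$iterations,
                              fdr = config$caller$fdr,
                              fdr_prob = config$caller$fdr_prob,
                              seed = config$seed)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      for (f in file.path(out, stage_outputs[[name]]))
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  res <- NULL
  run_stage("simulate", function() {
    write_toy_tracks(scn$toy, file.path(out, "tracks"))
    for (lib in names(scn$lib_specs)) {
      sim <- simulate_4c_library(scn$toy, scn$bait, scn$model,
                                 scn$lib_specs[[lib]], label = lib)
      write_pairs_fastq(sim$pairs,
                        file.path(out, sprintf("reads_%s_1.fastq", lib)),
                        file.path(out, sprintf("reads_%s_2.fastq", lib)))
    }
  })
  run_stage("demux", function() {
    res <<- analyse_scenario(scn,
                             qual_min = config$demux$qual_min,
                             len_min = config$demux$len_min,
                             k = config$profile$k,
                             min_tfs = config$enhancers$min_tfs,
                             max_dist = config$enhancers$max_dist)
    tallies <- do.call(rbind, lapply(names(res$demux), function(l)
      data.frame(library = l, stream = names(res$demux[[l]]),
                 n = as.integer(res$demux[[l]]))))
    utils::write.table(tallies, file.path(out, "demux_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  run_stage("quantify", function() {
    for (lib in c("rep1", "rep2", "control"))
      write_counts_tsv(res$counts[[lib]],
                       file.path(out, sprintf("counts_%s.tsv", lib)))
    reports <- do.call(rbind, lapply(c("rep1", "rep2"), function(l)
      data.frame(library = l, rule = names(res$counts[[l]]$filter_report),
                 reads = as.numeric(res$counts[[l]]$filter_report))))
    utils::write.table(reports, file.path(out, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  run_stage("profile", function() {
    for (lib in c("rep1", "rep2"))
      write_profile_bedgraph(res$profiles[[lib]],
                             file.path(out, sprintf("profile_%s.bedgraph", lib)))
    utils::write.table(res$cumulative, file.path(out, "cumulative_rep1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  run_stage("call", function() {
    for (lib in c("rep1", "rep2")) {
      iv <- summary(res$calls[[lib]])
      utils::write.table(iv, file.path(out, sprintf("calls_%s.tsv", lib)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  run_stage("overlap", function() {
    write_calls_bed(cbind(res$pooled,
                          category = pmax(res$pooled$cat1, res$pooled$cat2),
                          peak = 1),
                    file.path(out, "reproducible.bed"))
    utils::write.table(data.frame(side = names(res$domain_counts),
                                  n = as.integer(res$domain_counts)),
                      file.path(out, "domain_counts.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
  })
  run_stage("enhancers", function() {
    utils::write.table(res$candidates, file.path(out, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  manifest <- build_manifest(config, stage_outputs, out, skipped = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

build_manifest <- function(config, stage_outputs, out, skipped) {
  stages <- lapply(names(stage_outputs), function(st) {
    files <- file.path(out, stage_outputs[[st]])
    list(stage = st, skipped = skipped,
         artefacts = lapply(files, function(f)
           list(path = stage_outputs[[st]][match(f, files)],
                md5 = unname(tools::md5sum(f)))))
  })
  list(package = "fourcmap",
       seed = config$seed,
       library_seeds = list(rep1 = config$seed + 101L,
                            rep2 = config$seed + 202L,
                            control = config$seed + 303L,
                            caller_rep1 = config$seed,
                            caller_rep2 = config$seed + 17L),
       config = config[setdiff(names(config), "out_dir")],
       stages = stages)
}
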