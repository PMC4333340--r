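# End-to-end composition: simulate an F2 cross, exclusion-map the locus
# from the affected animals, refine by simulated recombinant progeny
# testing, and compute the incidence/laterality statistics. Deterministic
# given the seed; everything emitted is plain text plus a JSON manifest.

#' Default pipeline configuration
#'
#' @param seed integer seed (required for a reproducible run).
#' @param n_progeny F2 population size.
#' @param map a [genetic_map()] or TSV path; default the chromosome 14
#'   worked-example map.
#' @param causal_chrom,causal_pos_mb causal locus (default 34.96 Mb, the
#'   insertion-site position inside the 34.73-35.11 interval).
#' @param model a [penetrance_model()].
#' @param n_recombinants recombinant animals carried into progeny testing.
#' @param n_progeny_test backcross progeny simulated per recombinant.
#' @param tolerance phenocopy tolerance for the mapper.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, n_progeny = 1000L, map = NULL,
                       causal_chrom = "14", causal_pos_mb = 34.96,
                       model = penetrance_model(),
                       n_recombinants = 6L, n_progeny_test = 30L,
                       tolerance = 0L) {
  if (missing(seed) || !is.numeric(seed))
    stop("run_config: an integer seed is required")
  if (is.character(map)) map <- read_genetic_map(map)
  if (is.null(map)) map <- renag1_marker_map()
  structure(list(seed = as.integer(seed),
                 n_progeny = as.integer(n_progeny), map = map,
                 causal_chrom = causal_chrom,
                 causal_pos_mb = causal_pos_mb, model = model,
                 n_recombinants = as.integer(n_recombinants),
                 n_progeny_test = as.integer(n_progeny_test),
                 tolerance = as.integer(tolerance)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the simulate -> map -> progeny-test -> stats pipeline
#'
#' @param config a [run_config()].
#' @param out_prefix path prefix for the emitted artifact bundle; `NULL`
#'   computes everything in memory without writing files.
#' @return a `pipeline_run` list: the simulation, exclusion report, the
#'   progeny-test refinement (`NULL` when no recombinant conferred), the
#'   stats block, and (when written) the file manifest.
#' @export
run_pipeline <- function(config, out_prefix = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- stage("simulate", simulate_f2(
    config$n_progeny, config$map, config$model, config$causal_chrom,
    config$causal_pos_mb, seed = config$seed))

  aff <- sim$phenotypes$animal_id[sim$phenotypes$anomaly != "NONE"]
  if (length(aff) == 0L)
    stop("[stage mapping] no affected animals: nothing to map",
         call. = FALSE)
  report <- stage("mapping", map_dominant_exclusion(
    sim$genotypes[aff, , drop = FALSE], config$map, config$tolerance))

  refinement <- stage("progeny-testing", {
    prior <- if (length(report$intervals)) report$intervals[[1L]] else NULL
    sub <- map_chrom(config$map, config$causal_chrom)
    lo <- if (!is.null(prior) && prior$bounded_left) prior$left_mb
          else min(sub$pos_mb)
    hi <- if (!is.null(prior) && prior$bounded_right) prior$right_mb
          else max(sub$pos_mb)
    recs <- classify_recombinants(sim$genotypes[aff, , drop = FALSE],
                                  config$map, config$causal_chrom, lo, hi)
    rec_ids <- utils::head(recs$animal_id, config$n_recombinants)
    if (length(rec_ids) == 0L) NULL else {
      results <- list(); excl <- numeric(0)
      for (id in rec_ids) {
        i <- match(id, rownames(sim$genotypes))
        sire <- list(h1 = sim$truth$hap1[i, ], h2 = sim$truth$hap2[i, ])
        bc <- simulate_backcross(sire, sim$truth$loci, config$model,
                                 n = config$n_progeny_test,
                                 id_prefix = paste0(id, "-BC"))
        seg <- infer_donor_segment(
          sim$genotypes[id, sub$marker], config$map, animal_id = id)
        aff_bc <- bc$phenotypes$anomaly != "NONE"
        results[[id]] <- progeny_test_result(seg, config$n_progeny_test,
                                             sum(aff_bc))
        if (any(aff_bc)) {
          g <- bc$genotypes[aff_bc, , drop = FALSE]
          nn <- colnames(g)[apply(g == "N", 2L, any)]
          pos <- sub$pos_mb[match(nn, sub$marker)]
          excl <- c(excl, stats::setNames(pos, nn))
        }
      }
      if (any(vapply(results, `[[`, logical(1L), "confers")))
        intersect_conferring_segments(results, prior = prior,
                                      excluded_positions = excl)
      else NULL
    }
  })

  stats_block <- stage("stats", {
    ph <- sim$phenotypes
    n <- nrow(ph)
    ura <- ph[ph$anomaly == "URA", , drop = FALSE]
    uni <- ura[!is.na(ura$side) & ura$side != "BILATERAL", , drop = FALSE]
    list(overall = incidence(sum(ph$anomaly != "NONE"), n),
         by_class = lapply(stats::setNames(ANOMALY_CLASSES,
                                           ANOMALY_CLASSES),
                           function(cl) incidence(sum(ph$anomaly == cl),
                                                  n)),
         ura_right = if (nrow(uni))
           list(k = sum(uni$side == "RIGHT"), n = nrow(uni),
                p_value = side_bias_test(sum(uni$side == "RIGHT"),
                                         nrow(uni)))
         else NULL)
  })

  manifest <- NULL
  if (!is.null(out_prefix)) {
    manifest <- stage("write", write_bundle(config, sim, report,
                                            refinement, stats_block,
                                            out_prefix))
  }
  structure(list(config = config, sim = sim, exclusion = report,
                 refinement = refinement, stats = stats_block,
                 manifest = manifest),
            class = "pipeline_run")
}

interval_as_list <- function(iv) {
  if (is.null(iv)) return(NULL)
  iv[c("chrom", "left_marker", "right_marker", "left_mb", "right_mb",
       "bounded_left", "bounded_right", "width_mb", "n_support")]
}

write_bundle <- function(config, sim, report, refinement, stats_block,
                         out_prefix) {
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  f <- function(suffix) paste0(out_prefix, suffix)
  write_genetic_map(config$map, f("_map.tsv"))
  write_genotypes(sim$genotypes, f("_genotypes.tsv"))
  write_phenotypes(sim$phenotypes, f("_phenotypes.tsv"))
  utils::write.table(report$markers, f("_exclusion_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    intervals = lapply(report$intervals, interval_as_list),
    refinement = if (!is.null(refinement)) list(
      conservative = interval_as_list(refinement$conservative),
      minimal = interval_as_list(refinement$minimal),
      n_conferring = refinement$n_conferring),
    stats = list(
      overall = unclass(stats_block$overall),
      by_class = lapply(stats_block$by_class, unclass),
      ura_right = stats_block$ura_right))
  jsonlite::write_json(summary, f("_summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files <- paste0(out_prefix, c("_map.tsv", "_genotypes.tsv",
                                "_phenotypes.tsv", "_exclusion_report.tsv",
                                "_summary.json"))
  manifest <- list(
    package = "exclumap",
    version = as.character(utils::packageVersion("exclumap")),
    seed = config$seed,
    parameters = list(
      n_progeny = config$n_progeny, causal_chrom = config$causal_chrom,
      causal_pos_mb = config$causal_pos_mb,
      model = unclass(config$model),
      n_recombinants = config$n_recombinants,
      n_progeny_test = config$n_progeny_test,
      tolerance = config$tolerance),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, f("_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}
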