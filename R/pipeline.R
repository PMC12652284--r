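#' Configuration of an end-to-end analysis run
#'
#' Bundles every tunable of the pipeline with its standard default:
#' 5-bp/1-bp GC windows, 100 position bins, 0.75 smoother span, a 1-kb
#' tandem distance bound, and 0.9/0.8 identity/coverage clustering
#' thresholds.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving the simulation stage.
#' @param spec Optional \code{\link{synthetic_spec}}; defaults to
#'   \code{default_synthetic_spec(seed)}. Set \code{input_dir} instead
#'   to analyse an existing fixture directory.
#' @param input_dir Optional directory of an already written fixture
#'   (skips the simulate stage).
#' @param window,step GC profile window/step (bp).
#' @param bins,span Aggregation bins and smoother span.
#' @param max_gap Tandem distance bound (bp, strict).
#' @param min_id,min_cov Greedy clustering thresholds.
#' @param params \code{\link{scoring_params}}.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1L, spec = NULL,
                       input_dir = NULL, window = 5L, step = 1L,
                       bins = 100L, span = 0.75, max_gap = 1000L,
                       min_id = 0.90, min_cov = 0.80,
                       params = scoring_params()) {
  if (is.null(spec) && is.null(input_dir))
    spec <- default_synthetic_spec(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 spec = spec, input_dir = input_dir, window = window,
                 step = step, bins = bins, span = span,
                 max_gap = max_gap, min_id = min_id, min_cov = min_cov,
                 params = params),
            class = "run_config")
}

.stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) e)
  ok <- !inherits(res, "error")
  manifest$stages[[name]] <- list(
    status = if (ok) "ok" else "failed",
    seconds = round(proc.time()[["elapsed"]] - t0, 3),
    error = if (ok) NULL else conditionMessage(res))
  list(manifest = manifest, value = if (ok) res else NULL, ok = ok,
       error = if (ok) NULL else res)
}

#' Run the full simulate/ingest/stats/tandem/cluster/report pipeline
#'
#' Executes the six stages in order, writing all result tables under
#' \code{config$out_dir} and a JSON run manifest (stage status and
#' timings, per-table row counts, output checksums). Any stage error
#' writes a partial manifest and then aborts. Re-running an identical
#' configuration reproduces every output byte-identically except the
#' timing fields of the manifest.
#'
#' @param config \code{\link{run_config}}.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out) &&
      !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out, call. = FALSE)
  manifest <- list(seed = config$seed,
                   settings = list(window = config$window,
                                   step = config$step,
                                   bins = config$bins,
                                   span = config$span,
                                   max_gap = config$max_gap,
                                   min_id = config$min_id,
                                   min_cov = config$min_cov),
                   stages = list())
  finish <- function(manifest, failed = FALSE) {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (failed) stop("pipeline stage failed: see manifest at ", out,
                     call. = FALSE)
    invisible(manifest)
  }
  log_stage <- function(name)
    message("[", name, "] ", appendLF = FALSE)

  # 1. simulate (or reuse an existing fixture directory)
  log_stage("simulate")
  st <- .stage(manifest, "simulate", {
    if (!is.null(config$input_dir)) {
      if (!dir.exists(config$input_dir))
        stop("input directory not found: ", config$input_dir)
      config$input_dir
    } else {
      fix <- generate_fixture(config$spec)
      write_fixture(fix, file.path(out, "fixture"))
      file.path(out, "fixture")
    }
  })
  manifest <- st$manifest
  if (!st$ok) return(finish(manifest, failed = TRUE))
  fix_dir <- st$value
  message("done")

  # 2. ingest: round-trip through the tabular + FASTA readers
  log_stage("ingest")
  st <- .stage(manifest, "ingest", read_fixture(fix_dir))
  manifest <- st$manifest
  if (!st$ok) return(finish(manifest, failed = TRUE))
  annot <- st$value
  manifest$stages$ingest$n_genes <- nrow(annot$genes)
  message(nrow(annot$genes), " genes")

  # 3. conservation statistics
  log_stage("stats")
  st <- .stage(manifest, "stats", {
    genes <- annot$genes
    ab <- abundance_matrix(genes)
    istats <- intron_stats(genes)
    ld <- length_distribution(genes)
    prof <- gene_gc_profiles(genes, config$window, config$step)
    agg <- aggregate_gc(prof, config$bins, config$span)
    gs <- genome_sizes(annot)
    counts <- ab$species_totals[names(gs)]
    # the correlation needs at least three species to be meaningful
    corr <- if (length(gs) >= 3L) {
      genome_size_correlation(counts, gs)
    } else {
      list(r = NA_real_, p_value = NA_real_, r_squared = NA_real_,
           n = length(gs), note = "fewer than 3 species")
    }
    tabs <- list(
      abundance_matrix = ab$matrix,
      abundance_matrix_imet = ab$matrix65,
      intron_per_species = istats$per_species,
      intron_histogram = data.frame(
        length = as.integer(names(istats$histogram)),
        n = as.integer(istats$histogram)),
      length_histogram = data.frame(
        length = as.integer(names(ld$histogram)),
        n = as.integer(ld$histogram)),
      gc_aggregate = as.data.frame(agg))
    write_results(tabs, file.path(out, "stats"), summary = list(
      absent_anticodons = ab$absent,
      n_absent = length(ab$absent),
      intron_mode_bp = istats$mode_length,
      intron_mean_bp = istats$mean_length,
      length_modes_bp = ld$modes,
      genome_size_correlation = corr[c("r", "p_value", "r_squared",
                                       "n")]))
    list(ab = ab, corr = corr)
  })
  manifest <- st$manifest
  if (!st$ok) return(finish(manifest, failed = TRUE))
  message("done")

  # 4. tandem duplication detection, identical-only and all-pair modes
  log_stage("tandem")
  st <- .stage(manifest, "tandem", {
    pairs <- proximal_pairs(annot, config$max_gap)
    cls <- classify_pairs(pairs, annot, params = config$params)
    ident_clusters <- chain_clusters(cls, annot, mode = "identical")
    all_clusters <- chain_clusters(cls, annot, mode = "all")
    degen <- degenerate_anticodon_pairs(cls)
    ps <- pair_summary(cls)
    write_results(list(pairs = cls,
                       clusters_identical = ident_clusters,
                       clusters_all = all_clusters,
                       degenerate_pairs = degen$pairs,
                       degenerate_by_amino_acid = degen$by_amino_acid),
                  file.path(out, "tandem"),
                  summary = ps)
    list(pairs = cls, ident = ident_clusters, all = all_clusters,
         summary = ps)
  })
  manifest <- st$manifest
  if (!st$ok) return(finish(manifest, failed = TRUE))
  manifest$stages$tandem$n_pairs <- st$value$summary$n_pairs
  manifest$stages$tandem$n_identical <- st$value$summary$n_identical
  message(st$value$summary$n_pairs, " pairs")

  # 5. sequence-level clustering of unique sequences
  log_stage("cluster")
  st <- .stage(manifest, "cluster", {
    uq <- unique_sequences(annot$genes)
    seqs <- stats::setNames(uq$seq, uq$unique_name)
    cl <- greedy_cluster(seqs, config$min_id, config$min_cov,
                         config$params)
    write_results(list(unique_sequences = uq, greedy_clusters = cl),
                  file.path(out, "cluster"),
                  summary = list(n_unique = nrow(uq),
                                 n_clusters = length(unique(cl$cluster))))
    list(uq = uq, cl = cl)
  })
  manifest <- st$manifest
  if (!st$ok) return(finish(manifest, failed = TRUE))
  message(nrow(st$value$uq), " unique sequences")

  # 6. report: checksums over every emitted file
  log_stage("report")
  st <- .stage(manifest, "report", {
    files <- sort(list.files(out, recursive = TRUE, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    md5 <- tools::md5sum(files)
    data.frame(file = substring(files, nchar(out) + 2L),
               md5 = unname(md5), stringsAsFactors = FALSE)
  })
  manifest <- st$manifest
  if (!st$ok) return(finish(manifest, failed = TRUE))
  manifest$checksums <- st$value
  message("done")
  finish(manifest)
}
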