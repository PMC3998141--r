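PREQC_SCHEMA_VERSION <- "1.0"

#' Configuration for a full quality-assessment run
#'
#' Collects the per-metric sampling sizes and k grids used by
#' [run_all()]. Defaults are the full-scale sampling constants (50000
#' reads for count histograms, 100000 for the error profile, 1000000 for
#' branch scans, 100000 pairs for fragment sizes, 20000 assembly walks);
#' `scale` multiplies every sampling size for desk-scale runs.
#'
#' @param seed Integer; one global seed fanned out into per-stage
#'   substreams so metrics can be toggled without perturbing one another.
#' @param scale Multiplier applied to all sampling sizes.
#' @param k_genome_size k for genome-size estimation (default 31).
#' @param k_coverage k for the coverage histogram, GC histogram and
#'   fragment walks (default 51).
#' @param branch_k k grid for branch-rate estimation.
#' @param assembly_k k grid for simulated assembly.
#' @param n_hist_reads,n_error_reads,n_branch_reads,n_fragment_pairs,n_assembly_walks,n_quality_reads,n_gc_samples
#'   Per-metric sampling sizes before scaling.
#' @param metrics Character vector naming the stages to run; any of
#'   `"kmer_histogram"`, `"gc_coverage"`, `"genome_size"`,
#'   `"branch_rates"`, `"error_profile"`, `"quality_profile"`,
#'   `"fragment_sizes"`, `"sim_assembly"`.
#' @return A list of class `preqc_config`.
#' @export
preqc_config <- function(seed = 1, scale = 1, k_genome_size = 31,
                         k_coverage = 51,
                         branch_k = seq(21, 71, by = 5),
                         assembly_k = seq(21, 91, by = 5),
                         n_hist_reads = 50000, n_error_reads = 100000,
                         n_branch_reads = 1000000,
                         n_fragment_pairs = 100000,
                         n_assembly_walks = 20000,
                         n_quality_reads = 50000, n_gc_samples = 100000,
                         metrics = c("kmer_histogram", "gc_coverage",
                                     "genome_size", "branch_rates",
                                     "error_profile", "quality_profile",
                                     "fragment_sizes", "sim_assembly")) {
  sc <- function(x) max(1L, as.integer(ceiling(x * scale)))
  structure(list(seed = as.integer(seed), scale = scale,
                 k_genome_size = k_genome_size, k_coverage = k_coverage,
                 branch_k = branch_k, assembly_k = assembly_k,
                 n_hist_reads = sc(n_hist_reads),
                 n_error_reads = sc(n_error_reads),
                 n_branch_reads = sc(n_branch_reads),
                 n_fragment_pairs = sc(n_fragment_pairs),
                 n_assembly_walks = sc(n_assembly_walks),
                 n_quality_reads = sc(n_quality_reads),
                 n_gc_samples = sc(n_gc_samples),
                 metrics = metrics),
            class = "preqc_config")
}

.stage_seed <- function(config, stage_index) {
  (config$seed + 1009L * stage_index) %% .Machine$integer.max
}

#' Run all quality-assessment metrics on a read set
#'
#' Orchestrates the full pipeline: builds the shared k-mer index, then
#' runs each configured metric, logging timing per stage. A failing stage
#' is recorded in the report's `errors` field and the remaining stages
#' still run. Given identical reads and configuration the report is
#' reproducible byte for byte.
#'
#' @param reads A [read_set].
#' @param config A [preqc_config()].
#' @return An object of class `preqc_report`: a named list of sections
#'   ready for [write_report_json()].
#' @export
run_all <- function(reads, config = preqc_config()) {
  stopifnot(inherits(reads, "read_set"))
  if (n_reads(reads) == 0) stop("empty read set")
  report <- list(
    schema_version = PREQC_SCHEMA_VERSION,
    tool = list(name = "preqcr",
                version = as.character(utils::packageVersion("preqcr"))),
    parameters = unclass(config)[setdiff(names(unclass(config)), "metrics")],
    errors = list()
  )
  report$parameters$n_reads <- n_reads(reads)
  report$parameters$read_len <- modal_read_length(reads)
  report$parameters$paired <- reads$paired

  run_stage <- function(name, stage_index, fun) {
    if (!name %in% config$metrics) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    set.seed(.stage_seed(config, stage_index))
    res <- tryCatch(fun(), error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    message(sprintf("[preqcr] %-16s %6.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    if (!is.null(res)) report[[name]] <<- res
    invisible(NULL)
  }

  ks <- unique(c(config$k_genome_size, config$k_coverage))
  needs_seeds <- "error_profile" %in% config$metrics
  t0 <- proc.time()[["elapsed"]]
  idx <- build_kmer_index(reads, ks, with_k_plus_1 = TRUE,
                          seed_len = if (needs_seeds) 31 else 0)
  message(sprintf("[preqcr] %-16s %6.1f s", "index",
                  proc.time()[["elapsed"]] - t0))

  run_stage("kmer_histogram", 1L, function() {
    h <- kmer_count_histogram(idx, config$k_coverage, config$n_hist_reads)
    list(k = attr(h, "k"), count = h$count, freq = h$freq,
         n_sampled_reads = attr(h, "n_sampled_reads"))
  })
  run_stage("gc_coverage", 2L, function() {
    g <- gc_coverage_histogram(idx, config$k_coverage, config$n_gc_samples)
    list(k = g$k, gc_breaks = g$gc_breaks, count_bins = g$count_bins,
         counts = g$counts, n_sampled = g$n_sampled)
  })
  run_stage("genome_size", 3L, function() {
    h <- sample_count_histogram(idx, config$k_genome_size,
                                config$n_hist_reads)
    model <- fit_mixture_em(h)
    est <- estimate_genome_size(model, n_reads(reads),
                                modal_read_length(reads),
                                k = config$k_genome_size)
    list(G = est$G, lambda = est$lambda_used, w0 = est$w0_used,
         k = est$k_used,
         mixture_model = list(lambda = model$lambda,
                              lambda_e = model$lambda_e,
                              weights = model$weights,
                              loglik_trace = model$loglik_trace))
  })
  run_stage("branch_rates", 4L, function() {
    branch_rates(reads, k_values = config$branch_k,
                 n_sample_reads = config$n_branch_reads,
                 n_hist_reads = config$n_hist_reads)
  })
  run_stage("error_profile", 5L, function() {
    as.data.frame(per_base_error_rate(idx, config$n_error_reads))
  })
  run_stage("quality_profile", 6L, function() {
    quality_by_position(reads, config$n_quality_reads)
  })
  run_stage("fragment_sizes", 7L, function() {
    if (!reads$paired) stop("read set is not paired")
    fs <- estimate_fragment_sizes(idx, config$n_fragment_pairs,
                                  k = config$k_coverage)
    list(k = fs$k, sizes = fs$sizes, n_attempted = fs$n_attempted,
         n_resolved = fs$n_resolved)
  })
  run_stage("sim_assembly", 8L, function() {
    sa <- simulate_assembly(reads, k_values = config$assembly_k,
                            n_walks = config$n_assembly_walks,
                            n_hist_reads = config$n_hist_reads)
    sa$summary
  })
  structure(report, class = "preqc_report")
}

.sort_keys <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, .sort_keys)
  } else x
}

#' Write a report to a JSON file
#'
#' Keys are sorted and floats serialized with 12 significant digits, so
#' identical reports produce identical bytes.
#'
#' @param report A [run_all()] result (class `preqc_report`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "preqc_report") || is.list(report))
  out <- .sort_keys(unclass(report))
  json <- jsonlite::toJSON(out, digits = I(12), auto_unbox = TRUE,
                           pretty = TRUE, na = "null", dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' Read a report back from JSON
#'
#' Round-trips [write_report_json()] output; unknown extra keys are
#' preserved. A schema-version mismatch is an explicit error.
#'
#' @param path Path to a report JSON file.
#' @return A `preqc_report` list.
#' @export
read_report_json <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(rep$schema_version))
    stop("not a preqcr report: missing schema_version")
  if (!identical(as.character(rep$schema_version), PREQC_SCHEMA_VERSION))
    stop("report schema version ", rep$schema_version,
         " does not match supported version ", PREQC_SCHEMA_VERSION)
  structure(rep, class = "preqc_report")
}

.panel_missing <- function(title) {
  graphics::plot.new()
  graphics::title(main = title)
  graphics::text(0.5, 0.5, "metric not available", col = "grey40")
}

#' Render the report plots to a PDF
#'
#' One panel per section: 51-mer count spectrum, GC-by-count heat map,
#' branch rates versus k (variant and repeat), simulated contig N50
#' versus k, per-position error rate, quality by position and the
#' fragment-size distribution. Sections absent from the report render as
#' annotated empty panels. The report object is not modified.
#'
#' @param report A `preqc_report`.
#' @param path Output PDF path.
#' @return Invisibly, `path`.
#' @export
render_report <- function(report, path) {
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())

  h <- report$kmer_histogram
  if (!is.null(h)) {
    graphics::plot(h$count, h$freq, type = "h", log = "x",
                   xlab = "k-mer count", ylab = "frequency",
                   main = sprintf("%d-mer count spectrum", h$k))
  } else .panel_missing("k-mer count spectrum")

  g <- report$gc_coverage
  if (!is.null(g)) {
    m <- as.matrix(g$counts)
    graphics::image(x = g$gc_breaks, y = g$count_bins,
                    z = log1p(m), col = grDevices::hcl.colors(64, "YlOrRd",
                                                              rev = TRUE),
                    xlab = "GC fraction", ylab = "k-mer count",
                    main = "coverage by GC content")
  } else .panel_missing("coverage by GC content")

  br <- report$branch_rates
  if (!is.null(br) && any(!is.na(br$variant_rate) | !is.na(br$repeat_rate))) {
    rng <- range(c(br$variant_rate, br$repeat_rate), na.rm = TRUE)
    graphics::plot(br$k, br$variant_rate, type = "b", col = "forestgreen",
                   ylim = rng, log = if (all(rng > 0)) "y" else "",
                   xlab = "k", ylab = "branch rate",
                   main = "de Bruijn branch rates")
    graphics::lines(br$k, br$repeat_rate, type = "b", col = "steelblue")
    graphics::legend("topright", legend = c("variant", "repeat"),
                     col = c("forestgreen", "steelblue"), lty = 1)
  } else .panel_missing("de Bruijn branch rates")

  sa <- report$sim_assembly
  if (!is.null(sa)) {
    graphics::plot(sa$k, sa$n50, type = "b", xlab = "k",
                   ylab = "N50 (k-mers)", main = "simulated contig N50")
  } else .panel_missing("simulated contig N50")

  ep <- report$error_profile
  if (!is.null(ep)) {
    graphics::plot(ep$pos, 100 * ep$rate, type = "l", xlab = "read position",
                   ylab = "error rate (%)", main = "per-base error rate")
  } else .panel_missing("per-base error rate")

  qp <- report$quality_profile
  if (!is.null(qp)) {
    graphics::plot(qp$pos, qp$mean, type = "l", ylim = c(0, 45),
                   xlab = "read position", ylab = "Phred quality",
                   main = "quality by position")
    graphics::lines(qp$pos, qp$q10, lty = 2, col = "grey50")
    graphics::lines(qp$pos, qp$q90, lty = 2, col = "grey50")
  } else .panel_missing("quality by position")

  fs <- report$fragment_sizes
  if (!is.null(fs) && length(fs$sizes)) {
    graphics::hist(fs$sizes, breaks = 50, xlab = "fragment size (bp)",
                   main = "fragment-size distribution")
  } else .panel_missing("fragment-size distribution")

  gsz <- report$genome_size
  if (!is.null(gsz)) {
    graphics::plot.new()
    graphics::title(main = "genome size")
    graphics::text(0.5, 0.6, sprintf("estimated genome size: %.2f Mb",
                                     gsz$G / 1e6))
    graphics::text(0.5, 0.4, sprintf("lambda = %.1f, error k-mer fraction = %.3f",
                                     gsz$lambda, gsz$w0))
  } else .panel_missing("genome size")

  invisible(path)
}
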