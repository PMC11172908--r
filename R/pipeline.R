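# Allowed configuration schema: section -> known keys.
config_schema <- list(
  seed = NULL,
  out_dir = NULL,
  genome = c("chrom_lengths", "window_size", "mask_fraction"),
  cohort = c("group_sizes"),
  truth = c("region_specs"),
  simulation = c("mean_coverage", "gc_bias_peak", "gc_bias_strength",
                 "dispersion"),
  caller = c("loss_max", "gain_min", "min_windows", "max_gap_windows"),
  merge = c("min_variant_freq", "corr_min", "max_gap_windows",
            "merge_dist_windows", "min_call_windows"),
  filter = c("sil_min", "loss_max_len", "gain_max_len", "both_max_len"),
  vst = c("contrasts", "top_q"),
  annotation = c("n_genes", "exons_per_gene", "n_qtls")
)

#' Validate a pipeline configuration
#'
#' Rejects unknown sections and unknown keys within sections, naming the
#' offender; fills in nothing (defaults are applied by [run_pipeline()]).
#'
#' @param config nested list (see [demo_config()]) or path to a YAML file.
#' @return the validated config list, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown))
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    keys <- config_schema[[sec]]
    if (is.null(keys)) next
    bad <- setdiff(names(config[[sec]]), keys)
    if (length(bad))
      stop("validation error: unknown key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  if (is.null(config$seed)) stop("validation error: 'seed' is required")
  config
}

#' Demonstration configuration
#'
#' A small end-to-end run: two chromosomes of 2 Mb, five groups of four
#' samples, the stock planted-region layout, and the three local-vs-
#' commercial contrasts. Completes in well under two minutes.
#'
#' @param seed master seed.
#' @param out_dir output directory for [run_pipeline()].
#' @return a config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("popcnv_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    genome = list(chrom_lengths = list(chr1 = 2e6, chr2 = 2e6),
                  window_size = 800, mask_fraction = 0.02),
    cohort = list(group_sizes = list(RC = 4, T = 4, WZS = 4, YL = 4, LR = 4)),
    simulation = list(mean_coverage = 50, gc_bias_peak = 0.35,
                      gc_bias_strength = 1.2, dispersion = 0.003),
    vst = list(contrasts = list(list(focal = "RC", ref = c("YL", "LR")),
                                list(focal = "T", ref = c("YL", "LR")),
                                list(focal = "WZS", ref = c("YL", "LR"))),
               top_q = 0.05),
    annotation = list(n_genes = 30, exons_per_gene = 3, n_qtls = 10)
  )
}

cfg_get <- function(config, sec, key, default) {
  v <- config[[sec]][[key]]
  if (is.null(v)) default else v
}

#' Run the full pipeline: simulate, call, build, scan, annotate
#'
#' Executes the five stages in order, writing every stage's outputs as TSV
#' into `config$out_dir` together with a JSON manifest recording each
#' stage's parameters (and a hash of them). Reruns with the same config are
#' byte-identical. A stage failure halts the run with the failing stage
#' named; outputs of completed stages are retained.
#'
#' @param config nested list or YAML path; see [demo_config()] and
#'   [validate_config()].
#' @return (invisibly) a list with the in-memory results of every stage and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  seed <- config$seed
  out_dir <- if (is.null(config$out_dir)) tempfile("popcnv_run_") else
    config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(seed = seed, stages = list())
  note <- function(stage, params, outputs) {
    js <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
    h <- fnv1a(as.character(js))
    manifest$stages[[stage]] <<- list(
      params = params,
      param_hash = sprintf("%04x%04x", as.integer(h %/% 65536),
                           as.integer(h %% 65536)),
      outputs = outputs)
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- stage 1: simulate ---------------------------------------------------
  sim <- run_stage("simulate", function() {
    chrom_lengths <- unlist(cfg_get(config, "genome", "chrom_lengths",
                                    list(chr1 = 2e6, chr2 = 2e6)))
    genome <- make_windowed_genome(
      chrom_lengths,
      window_size = cfg_get(config, "genome", "window_size", 800),
      gc_profile_seed = derive_seed(seed, "genome"),
      mask_fraction = cfg_get(config, "genome", "mask_fraction", 0.02))
    group_sizes <- unlist(cfg_get(
      config, "cohort", "group_sizes",
      list(RC = 4, T = 4, WZS = 4, YL = 4, LR = 4)))
    specs <- config$truth$region_specs
    if (is.null(specs)) specs <- default_region_specs(genome,
                                                      groups = names(group_sizes))
    truth <- plant_truth(genome, group_sizes, specs,
                         seed = derive_seed(seed, "truth"))
    depth <- simulate_depth(
      genome, truth,
      mean_coverage = cfg_get(config, "simulation", "mean_coverage", 50),
      gc_bias = c(peak = cfg_get(config, "simulation", "gc_bias_peak", 0.35),
                  strength = cfg_get(config, "simulation", "gc_bias_strength", 1.2)),
      dispersion = cfg_get(config, "simulation", "dispersion", 0.003),
      seed = derive_seed(seed, "depth"))
    annotation <- emit_annotations(
      genome,
      n_genes = cfg_get(config, "annotation", "n_genes", 30),
      exons_per_gene = cfg_get(config, "annotation", "exons_per_gene", 3),
      n_qtls = cfg_get(config, "annotation", "n_qtls", 10),
      seed = derive_seed(seed, "annotation"))
    write_windows(genome, file.path(out_dir, "windows.bed"))
    write_tsv(truth$regions, file.path(out_dir, "truth_regions.tsv"))
    write_tsv(truth$carriers, file.path(out_dir, "truth_carriers.tsv"))
    write_tsv(truth$sample_groups, file.path(out_dir, "samples.tsv"))
    write_depth_matrix(depth, file.path(out_dir, "depth.tsv"))
    write_tsv(annotation$genes, file.path(out_dir, "genes.bed"))
    write_tsv(annotation$exons, file.path(out_dir, "exons.bed"))
    write_tsv(annotation$qtls, file.path(out_dir, "qtl.bed"))
    list(genome = genome, truth = truth, depth = depth,
         annotation = annotation)
  })
  note("simulate",
       list(genome = config$genome, cohort = config$cohort,
            simulation = config$simulation, annotation = config$annotation),
       c("windows.bed", "truth_regions.tsv", "truth_carriers.tsv",
         "samples.tsv", "depth.tsv", "genes.bed", "exons.bed", "qtl.bed"))

  # --- stage 2: depth calling ----------------------------------------------
  caller_par <- list(
    loss_max = cfg_get(config, "caller", "loss_max", 1.5),
    gain_min = cfg_get(config, "caller", "gain_min", 2.5),
    min_windows = cfg_get(config, "caller", "min_windows", 2),
    max_gap_windows = cfg_get(config, "caller", "max_gap_windows", 1))
  depthcall <- run_stage("depthcall", function() {
    corrected <- gc_correct(sim$depth, sim$genome)
    cn <- normalize_copy_number(corrected, sim$genome)
    calls <- call_sample_cnvs(cn, sim$genome,
                              loss_max = caller_par$loss_max,
                              gain_min = caller_par$gain_min,
                              min_windows = caller_par$min_windows,
                              max_gap_windows = caller_par$max_gap_windows)
    write_depth_matrix(round(cn, 4), file.path(out_dir, "cn.tsv"))
    write_calls(calls, file.path(out_dir, "calls.bed"))
    list(cn = cn, calls = calls)
  })
  note("depthcall", caller_par, c("cn.tsv", "calls.bed"))

  # --- stage 3: CNVR construction ------------------------------------------
  cfg_merge <- merge_config(
    min_variant_freq = cfg_get(config, "merge", "min_variant_freq", 0.05),
    corr_min = cfg_get(config, "merge", "corr_min", 0.5),
    max_gap_windows = cfg_get(config, "merge", "max_gap_windows", 1),
    merge_dist_windows = cfg_get(config, "merge", "merge_dist_windows", 3),
    min_call_windows = cfg_get(config, "merge", "min_call_windows", 3))
  filter_par <- list(
    sil_min = cfg_get(config, "filter", "sil_min", 0.6),
    loss_max_len = cfg_get(config, "filter", "loss_max_len", 50000),
    gain_max_len = cfg_get(config, "filter", "gain_max_len", 500000),
    both_max_len = cfg_get(config, "filter", "both_max_len", 50000))
  cnvr_stage <- run_stage("cnvr", function() {
    cs <- build_cnvrs(depthcall$cn, sim$genome, calls = depthcall$calls,
                      cfg = cfg_merge,
                      sil_min = filter_par$sil_min,
                      loss_max_len = filter_par$loss_max_len,
                      gain_max_len = filter_par$gain_max_len,
                      both_max_len = filter_par$both_max_len)
    write_tsv(cs$cnvrs, file.path(out_dir, "cnvrs.tsv"))
    geno <- data.frame(cnvr_id = rownames(cs$geno_int), cs$geno_int,
                       check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(geno, file.path(out_dir, "genotypes.tsv"))
    cs
  })
  note("cnvr", c(unclass(cfg_merge), filter_par),
       c("cnvrs.tsv", "genotypes.tsv"))

  # --- stage 4: Vst scan ---------------------------------------------------
  contrasts <- cfg_get(config, "vst", "contrasts",
                       list(list(focal = "RC", ref = c("YL", "LR")),
                            list(focal = "T", ref = c("YL", "LR")),
                            list(focal = "WZS", ref = c("YL", "LR"))))
  top_q <- cfg_get(config, "vst", "top_q", 0.05)
  vst_stage <- run_stage("vst", function() {
    records <- vst_scan(cnvr_stage$geno_real, sim$truth$sample_groups,
                        contrasts, q = top_q)
    panel <- group_frequency_panel(cnvr_stage$geno_int,
                                   sim$truth$sample_groups)
    write_tsv(records, file.path(out_dir, "vst.tsv"))
    write_tsv(panel, file.path(out_dir, "group_frequencies.tsv"))
    list(records = records, panel = panel)
  })
  note("vst", list(contrasts = contrasts, top_q = top_q),
       c("vst.tsv", "group_frequencies.tsv"))

  # --- stage 5: annotation & summaries -------------------------------------
  annotate_stage <- run_stage("annotate", function() {
    cnvrs <- cnvr_stage$cnvrs
    ctx <- genomic_context(cnvrs, sim$annotation)
    genes <- overlap_genes(cnvrs, sim$annotation)
    qtl <- overlap_qtls(cnvrs, sim$annotation$qtls)
    chrom <- chromosome_summary(cnvrs, sim$genome$chrom_lengths)
    stats <- summary_stats(calls = depthcall$calls, cnvrs = cnvrs,
                           chrom_lengths = sim$genome$chrom_lengths)
    write_tsv(data.frame(cnvr_id = cnvrs$id, context = ctx,
                         stringsAsFactors = FALSE),
              file.path(out_dir, "context.tsv"))
    write_tsv(genes, file.path(out_dir, "gene_overlaps.tsv"))
    write_tsv(qtl$overlaps, file.path(out_dir, "qtl_overlaps.tsv"))
    write_tsv(chrom$per_chrom, file.path(out_dir, "chromosome_counts.tsv"))
    jsonlite::write_json(stats, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(context = ctx, gene_overlaps = genes, qtl_overlaps = qtl,
         chromosome = chrom, stats = stats)
  })
  note("annotate", list(), c("context.tsv", "gene_overlaps.tsv",
                             "qtl_overlaps.tsv", "chromosome_counts.tsv",
                             "summary.json"))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = out_dir, sim = sim, depthcall = depthcall,
                 cnvrs = cnvr_stage, vst = vst_stage,
                 annotate = annotate_stage, manifest = manifest))
}
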