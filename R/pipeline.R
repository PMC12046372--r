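# Orchestration: the full scan (Hp/ZHp, iHS, FST/ZFST, XP-EHH -> outlier
# windows -> regions -> support table -> gene overlap) as one call.

#' Full-scan configuration
#'
#' Inputs can be file paths (`vcf`, `popmap`, ...) or in-memory objects
#' via `data` (a list as returned by [simulate_wf()]). Contrasts default
#' to every hot-by-cold population pair from the population map's group
#' labels.
#'
#' @param vcf,popmap,genmap,genes Input file paths (VCF, population map,
#'   PLINK .map, GFF3). Ignored when `data` is given.
#' @param data Optional list with `haplotypes`, `popmap`, optional
#'   `genmap`, optional `genes` (data frame).
#' @param contrasts List of `c(popA, popB)` pairs; default all hot x cold.
#' @param window_size,step,min_snps Window geometry (defaults 20 kb /
#'   10 kb / 20 SNPs).
#' @param chrom_length Chromosome length; default the last SNP position.
#' @param cutoff,bins,maf_min Haplotype-scan parameters (EHH cutoff,
#'   iHS frequency bins, core MAF).
#' @param ancestral Ancestral-allele policy for iHS (see [ihs_scan()]).
#' @param window_mode `"abs"` or `"signed"` window means for iHS/XP-EHH.
#' @param q Named tail fractions per method (default 0.001 each).
#' @param merge_gap Merge gap in bp (default 0: book-ended windows merge).
#' @param run_qc Apply MAF/call-rate filtering first (LD pruning is never
#'   implicit).
#' @param qc A [qc_config()] when `run_qc = TRUE`.
#' @param out_dir Output directory (required by [run_full_scan()]).
#' @return A `RunConfig`.
#' @export
run_config <- function(vcf = NULL, popmap = NULL, genmap = NULL,
                       genes = NULL, data = NULL, contrasts = NULL,
                       window_size = 20000L, step = 10000L, min_snps = 20L,
                       chrom_length = NULL, cutoff = 0.05, bins = 50L,
                       maf_min = 0.05, ancestral = "flag",
                       window_mode = c("abs", "signed"),
                       q = c(ZHp = 0.001, iHS = 0.001, ZFST = 0.001,
                             XPEHH = 0.001),
                       merge_gap = 0L, run_qc = FALSE, qc = qc_config(),
                       out_dir = NULL) {
  window_mode <- match.arg(window_mode)
  qq <- c(ZHp = 0.001, iHS = 0.001, ZFST = 0.001, XPEHH = 0.001)
  qq[names(q)] <- q
  structure(list(vcf = vcf, popmap = popmap, genmap = genmap,
                 genes = genes, data = data, contrasts = contrasts,
                 window_size = as.integer(window_size),
                 step = as.integer(step), min_snps = as.integer(min_snps),
                 chrom_length = chrom_length, cutoff = cutoff,
                 bins = as.integer(bins), maf_min = maf_min,
                 ancestral = ancestral, window_mode = window_mode,
                 q = qq, merge_gap = as.integer(merge_gap),
                 run_qc = run_qc, qc = qc, out_dir = out_dir),
            class = "RunConfig")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full selection-signature scan
#'
#' Executes: (optional QC) -> window grid -> Hp/ZHp per population ->
#' iHS per population (on the missing-free SNP subset) -> FST/ZFST and
#' XP-EHH per contrast -> extreme-percentile outlier calling -> region
#' consolidation -> cross-context support table (regions backed by at
#' least two method/context combinations) -> gene-overlap annotation.
#' Every track and region set is written under `out_dir`, and the run
#' manifest (scored-window counts, region counts, file checksums) both
#' returned and written as JSON. Deterministic for fixed inputs and
#' config.
#'
#' @param cfg A [run_config()] with `out_dir` set.
#' @return Invisibly, a list: `manifest`, `tracks`, `regions` (named list
#'   of `CandidateRegions`), `support`, `gene_table` (or `NULL`).
#' @export
run_full_scan <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (is.null(cfg$out_dir)) stop("out_dir must be set")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  inp <- stage("input", {
    if (!is.null(cfg$data)) cfg$data
    else list(haplotypes = read_phased_vcf(cfg$vcf),
              popmap = read_population_map(cfg$popmap),
              genmap = if (!is.null(cfg$genmap)) read_genetic_map(cfg$genmap),
              genes = if (!is.null(cfg$genes))
                read_gene_annotation(cfg$genes, "gff3"))
  })
  h <- inp$haplotypes
  popmap <- inp$popmap
  genmap <- inp$genmap
  pops <- unique(popmap$assignments)

  contrasts <- cfg$contrasts
  if (is.null(contrasts)) {
    hot <- names(popmap$groups)[popmap$groups == "hot"]
    cold <- names(popmap$groups)[popmap$groups == "cold"]
    contrasts <- unlist(lapply(hot, function(a) lapply(cold, function(b)
      c(a, b))), recursive = FALSE)
  }
  stage("validate", {
    for (ct in contrasts)
      if (!all(ct %in% pops))
        stop("contrast references undeclared population(s): ",
             paste(setdiff(ct, pops), collapse = ", "))
    if (!all(names(popmap$assignments) %in% h$sample_ids))
      stop("population map lists samples absent from the VCF")
  })

  if (isTRUE(cfg$run_qc))
    h <- stage("qc", filter_variants(h, cfg$qc)$haplotypes)

  chrom_length <- cfg$chrom_length
  if (is.null(chrom_length)) chrom_length <- max(h$positions)
  grid <- stage("windows",
                assign_snps(build_window_grid(chrom_length,
                                              cfg$window_size, cfg$step,
                                              cfg$min_snps, h$chrom), h))
  hc <- stage("missing-prepass", drop_missing_variants(h))

  tracks <- list()
  for (p in pops) {
    smp <- labelled_samples(pop_samples(popmap, p), p)
    tracks[[paste0("ZHp_", p)]] <-
      stage(paste0("hp:", p), z_standardize(window_hp(h, smp, grid)))
    scores <- stage(paste0("ihs:", p),
                    ihs_scan(hc, smp, genmap, cfg$maf_min, cfg$cutoff,
                             cfg$bins, cfg$ancestral))
    tracks[[paste0("iHS_", p)]] <-
      window_mean_scores(scores, grid, cfg$window_mode)
  }
  for (ct in contrasts) {
    lab <- paste(ct, collapse = "~")
    comps <- stage(paste0("fst:", lab),
                   wc_fst_components(h, pop_samples(popmap, ct[1L]),
                                     pop_samples(popmap, ct[2L])))
    tracks[[paste0("ZFST_", lab)]] <-
      stage(paste0("zfst:", lab),
            z_standardize(windowed_fst(comps, grid, ct)))
    hA <- subset_haplotypes(hc, pop_samples(popmap, ct[1L]))
    hB <- subset_haplotypes(hc, pop_samples(popmap, ct[2L]))
    xscores <- stage(paste0("xpehh:", lab),
                     xpehh_scan(hA, hB, genmap, cfg$cutoff))
    xscores <- `attr<-`(xscores, "context", lab)
    tracks[[paste0("XPEHH_", lab)]] <-
      window_mean_scores(xscores, grid, cfg$window_mode)
  }

  method_of <- function(name) sub("_.*$", "", name)
  tail_of <- function(method) if (method == "ZHp") "low" else "high"
  regions <- list()
  for (nm in names(tracks)) {
    meth <- method_of(nm)
    if (!any(!is.na(tracks[[nm]]$values))) {
      # e.g. iHS on data where every core is truncated: no scored window
      message("track ", nm, " has no scored windows; no regions called")
      regions[[nm]] <- merge_regions(
        data.frame(chrom = character(), start = integer(),
                   end = integer(), value = numeric()))
      next
    }
    rule <- outlier_rule(meth, tail_of(meth), cfg$q[[meth]])
    wins <- stage(paste0("call:", nm),
                  suppressWarnings(call_outlier_windows(tracks[[nm]], rule)))
    regions[[nm]] <- merge_regions(wins, cfg$merge_gap)
  }

  nonempty <- regions[vapply(regions, nrow, integer(1)) > 0L]
  support <- if (length(nonempty) >= 2L)
    stage("support", intersect_contexts(unname(nonempty), "k_of_n", k = 2L))
  else data.frame(chrom = character(), start = integer(), end = integer(),
                  support = character(), n_support = integer())

  all_regions <- do.call(rbind, c(unname(regions), make.row.names = FALSE))
  gene_table <- NULL
  if (!is.null(inp$genes) && nrow(all_regions))
    gene_table <- stage("annotate", annotate_genes(all_regions, inp$genes))

  # write outputs
  files <- character(0)
  for (nm in names(tracks)) {
    f <- file.path(cfg$out_dir, paste0("track_", gsub("[^A-Za-z0-9_.~-]", "_", nm), ".tsv"))
    write_track(tracks[[nm]], f)
    files <- c(files, f)
  }
  rf <- file.path(cfg$out_dir, "regions.tsv")
  utils::write.table(all_regions, rf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bf <- file.path(cfg$out_dir, "regions.bed")
  write_regions_bed(all_regions, bf)
  sf <- file.path(cfg$out_dir, "support.tsv")
  utils::write.table(support, sf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, rf, bf, sf)
  if (!is.null(gene_table)) {
    gf <- file.path(cfg$out_dir, "gene_overlaps.tsv")
    utils::write.table(gene_table, gf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, gf)
  }

  manifest <- list(
    n_samples = n_samples(h), n_variants = n_variants(h),
    n_windows = n_windows(grid),
    scored_windows = lapply(tracks, function(t) sum(!is.na(t$values))),
    region_counts = lapply(regions, nrow),
    n_support_regions = nrow(support),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, tracks = tracks, regions = regions,
                 support = support, gene_table = gene_table))
}
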