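# Forward-in-time Wright-Fisher island-model simulator with an optional
# hard selective sweep. Desk-scale by design: small demes, short
# chromosomes, mutation/recombination rates scaled up to reach realistic
# SNP densities (documented in the methods vignette).

#' Simulation configuration
#'
#' Parameterizes [simulate_wf()]: a symmetric island model of `n_demes`
#' Wright-Fisher demes of `deme_size` diploids evolving for `generations`
#' generations along a chromosome of `chrom_length` bp, with
#' infinite-sites mutation (`mu` per bp per generation), uniform
#' crossover recombination (`rec` per bp per generation; crossovers per
#' meiosis ~ Poisson(rec * chrom_length)) and symmetric migration
#' (`migration` per individual per generation). The optional hard sweep
#' places a single-copy beneficial mutation in one deme with additive
#' fitness 1, 1+s, 1+2s and is re-attempted from the introduction
#' generation (incremented sub-seed, bounded retries) until its final
#' frequency reaches `require_established`.
#'
#' @param n_demes Number of demes (default 2).
#' @param deme_size Diploids per deme (default 80).
#' @param sample_size Diploids sampled per deme at the end (default 20).
#' @param chrom_length Chromosome length in bp (default 3e5).
#' @param mu Mutation rate per bp per generation (default 2e-6; scaled up
#'   for desk-scale chromosomes to reach ~4-5 SNPs/kb in a sample).
#' @param rec Recombination rate per bp per generation (default 1e-6,
#'   chosen so a hard sweep's hitchhiking footprint — roughly
#'   `1 / (rec * time the allele spends at low frequency)` per side —
#'   spans one to three 20-kb scan windows rather than the whole
#'   desk-scale chromosome).
#' @param migration Migration rate per individual per generation
#'   (default 0.006, i.e. 4Nm near 2 at the default deme size: genome
#'   background FST around 0.1-0.2, stable enough across windows for
#'   empirical outlier calling, yet slow enough that post-sweep migrant
#'   influx does not refill the swept region's diversity before
#'   sampling; see the methods vignette for the calibration rationale).
#' @param generations Generations to simulate (default 500).
#' @param sweep List overriding any of: `enabled` (FALSE), `deme` (1),
#'   `position` (chrom midpoint), `s` (0.1), `intro_gen`
#'   (`generations - 75`, roughly one conditioned sweep duration before
#'   sampling so the allele is established but not long fixed),
#'   `require_established` (0.9), `max_retries` (100).
#' @param seed Mandatory integer seed; all randomness flows from it
#'   through named substreams (demography, sweep attempts, sampling).
#' @return A `SimConfig`.
#' @export
sim_config <- function(n_demes = 2L, deme_size = 80L, sample_size = 20L,
                       chrom_length = 3e5, mu = 2e-6, rec = 1e-6,
                       migration = 0.006, generations = 500L,
                       sweep = list(), seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  sw <- list(enabled = FALSE, deme = 1L,
             position = round(chrom_length / 2), s = 0.1,
             intro_gen = max(1L, as.integer(generations) - 75L),
             require_established = 0.9, max_retries = 100L)
  stopifnot(all(names(sweep) %in% names(sw)))
  sw[names(sweep)] <- sweep
  stopifnot(n_demes >= 1L, deme_size >= 2L, sample_size <= deme_size,
            mu >= 0, rec >= 0, migration >= 0, migration <= 1,
            generations >= 1L, chrom_length >= 1000,
            sw$position >= 1, sw$position <= chrom_length, sw$s >= 0,
            sw$intro_gen >= 1L, sw$intro_gen <= generations)
  structure(list(n_demes = as.integer(n_demes),
                 deme_size = as.integer(deme_size),
                 sample_size = as.integer(sample_size),
                 chrom_length = as.numeric(chrom_length), mu = mu,
                 rec = rec, migration = migration,
                 generations = as.integer(generations), sweep = sw,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a Wright-Fisher island model with an optional hard sweep
#'
#' Forward simulation: each generation every offspring haplotype is a
#' recombinant mosaic of one parent's two haplotypes (parents drawn
#' proportional to additive fitness when the sweep is active), a
#' Binomial(N, m) subset of each deme is replaced by migrants, and new
#' biallelic sites arise under the infinite-sites model (collisions
#' redrawn). Lost and globally fixed sites are pruned each generation
#' (the sweep site is tracked throughout). If the sweep allele's final
#' frequency in its deme is below `require_established`, the sweep phase
#' restarts from the introduction generation with an incremented
#' sub-seed (bounded by `max_retries`).
#'
#' @param cfg A [sim_config()].
#' @return List with `haplotypes` (a `HaplotypeSet` of the sampled
#'   diploids; ancestral allele = REF by construction), `popmap`
#'   (`PopulationMap`; the sweep deme is labelled `hot`, others `cold`),
#'   `genmap` (constant 1 cM/Mb `GeneticMap`), `truth` (sweep position,
#'   realized frequency trajectory, final deme and sample frequencies,
#'   attempts) and `config`.
#' @export
simulate_wf <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  nD <- cfg$n_demes; N <- cfg$deme_size; L <- cfg$chrom_length
  n2 <- 2L * N
  nrows <- nD * n2
  # budget guards: refuse configurations that would not finish at desk scale
  if (nrows * cfg$generations > 2e6)
    stop("budget guard: n_demes * 2 * deme_size * generations too large")
  if (cfg$mu * L * nrows > 2000)
    stop("budget guard: expected mutations per generation too large")

  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 200L, 3L)
  sw <- cfg$sweep

  H <- matrix(integer(0), nrow = nrows, ncol = 0L)
  pos <- numeric(0)
  sc <- NA_integer_
  traj <- numeric(0)

  deme_rows <- function(d) ((d - 1L) * n2 + 1L):(d * n2)

  step_gen <- function(gen, sel) {
    m <- ncol(H)
    # sweep introduction: single copy on a random haplotype of the deme
    if (sw$enabled && gen == sw$intro_gen && is.na(sc)) {
      col <- matrix(0L, nrows, 1L)
      col[(sw$deme - 1L) * n2 + sample.int(n2, 1L), 1L] <- 1L
      H <<- cbind(H, col)
      pos <<- c(pos, sw$position)
      sc <<- length(pos)
      m <- ncol(H)
    }
    new_rows <- integer(nrows)
    recombs <- list()
    for (d in seq_len(nD)) {
      off <- (d - 1L) * n2
      w <- rep(1, N)
      if (sel && !is.na(sc) && d == sw$deme) {  # beneficial only in its deme
        dose <- H[off + 2L * seq_len(N) - 1L, sc] +
          H[off + 2L * seq_len(N), sc]
        w <- 1 + sw$s * dose
      }
      par <- sample.int(N, n2, replace = TRUE, prob = w)
      nx <- stats::rpois(n2, cfg$rec * L)
      st <- sample.int(2L, n2, replace = TRUE) - 1L
      new_rows[off + seq_len(n2)] <- off + 2L * par - 1L + st
      for (g in which(nx > 0L)) {
        recombs[[length(recombs) + 1L]] <-
          list(row = off + g, parent = off + 2L * par[g] - 1L,
               st = st[g], nx = nx[g])
      }
    }
    newH <- H[new_rows, , drop = FALSE]
    for (rc in recombs) {
      b <- sort(stats::runif(rc$nx, 0, L))
      take_b <- (findInterval(pos, b) + rc$st) %% 2L == 1L
      v <- H[rc$parent, ]
      v[take_b] <- H[rc$parent + 1L, take_b]
      newH[rc$row, ] <- v
    }
    # migration: replace a Binomial(N, m) subset of each deme with copies
    # of random individuals from the other demes (island model)
    if (nD > 1L && cfg$migration > 0) {
      slots_all <- integer(0); src_all <- integer(0)
      for (d in seq_len(nD)) {
        k <- stats::rbinom(1L, N, cfg$migration)
        if (k == 0L) next
        slots <- (d - 1L) * N + sample.int(N, k)
        srcd <- (seq_len(nD)[-d])[sample.int(nD - 1L, k, replace = TRUE)]
        srci <- sample.int(N, k, replace = TRUE)
        slots_all <- c(slots_all, slots)
        src_all <- c(src_all, (srcd - 1L) * N + srci)
      }
      if (length(slots_all)) {
        src_rows <- as.vector(rbind(2L * src_all - 1L, 2L * src_all))
        dst_rows <- as.vector(rbind(2L * slots_all - 1L, 2L * slots_all))
        block <- newH[src_rows, , drop = FALSE]  # snapshot before writes
        newH[dst_rows, ] <- block
      }
    }
    # infinite-sites mutation, collisions redrawn
    mu_pos <- numeric(0); mu_row <- integer(0)
    for (d in seq_len(nD)) {
      nmut <- stats::rpois(1L, cfg$mu * L * n2)
      if (nmut == 0L) next
      taken <- c(pos, mu_pos, sw$position)
      cand <- sample.int(L, nmut, replace = TRUE)
      bad <- cand %in% taken | duplicated(cand)
      while (any(bad)) {
        cand[bad] <- sample.int(L, sum(bad), replace = TRUE)
        bad <- cand %in% taken | duplicated(cand)
      }
      mu_pos <- c(mu_pos, cand)
      mu_row <- c(mu_row, (d - 1L) * n2 + sample.int(n2, nmut,
                                                     replace = TRUE))
    }
    if (length(mu_pos)) {
      block <- matrix(0L, nrows, length(mu_pos))
      block[cbind(mu_row, seq_along(mu_pos))] <- 1L
      newH <- cbind(newH, block)
      pos <<- c(pos, mu_pos)
    }
    # prune lost and globally fixed sites; always keep the sweep site
    cnt <- colSums(newH)
    keep <- cnt > 0L & cnt < nrows
    sc_now <- if (is.na(sc)) NA_integer_ else match(sw$position, pos)
    if (!is.na(sc_now)) keep[sc_now] <- TRUE
    H <<- newH[, keep, drop = FALSE]
    pos <<- pos[keep]
    sc <<- if (is.na(sc)) NA_integer_ else match(sw$position, pos)
    if (!is.na(sc))
      traj <<- c(traj, sum(H[deme_rows(sw$deme), sc]) / n2)
    invisible(NULL)
  }

  attempts <- 0L
  if (!sw$enabled) {
    set.seed(seeds[1L])
    for (gen in seq_len(cfg$generations)) step_gen(gen, sel = FALSE)
  } else {
    set.seed(seeds[1L])
    gen <- 1L
    while (gen < sw$intro_gen) { step_gen(gen, sel = FALSE); gen <- gen + 1L }
    chk_H <- H; chk_pos <- pos
    repeat {
      attempts <- attempts + 1L
      if (attempts > sw$max_retries)
        stop("sweep failed to establish within ", sw$max_retries,
             " retries")
      set.seed((seeds[2L] + attempts))
      H <- chk_H; pos <- chk_pos; sc <- NA_integer_; traj <- numeric(0)
      for (gen in sw$intro_gen:cfg$generations) {
        step_gen(gen, sel = TRUE)
        # most attempts lose the allele within a few generations; abort
        # the attempt as soon as it is lost instead of simulating on
        if (is.na(sc) || traj[length(traj)] == 0) break
      }
      final <- if (is.na(sc)) 0 else
        sum(H[deme_rows(sw$deme), sc]) / n2
      if (final >= sw$require_established) break
    }
  }

  # sample diploids per deme and build the HaplotypeSet
  set.seed(seeds[3L])
  samp_rows <- integer(0); sample_ids <- character(0)
  assignments <- character(0)
  for (d in seq_len(nD)) {
    ind <- sort(sample.int(N, cfg$sample_size))
    ids <- sprintf("pop%d_s%02d", d, seq_len(cfg$sample_size))
    sample_ids <- c(sample_ids, ids)
    assignments <- c(assignments,
                     stats::setNames(rep(paste0("pop", d), length(ids)), ids))
    gind <- (d - 1L) * N + ind
    samp_rows <- c(samp_rows, as.vector(rbind(2L * gind - 1L, 2L * gind)))
  }
  S <- H[samp_rows, , drop = FALSE]
  cnt <- colSums(S)
  poly <- cnt > 0L & cnt < nrow(S)
  ord <- order(pos[poly])
  keep_cols <- which(poly)[ord]
  S <- S[, keep_cols, drop = FALSE]
  spos <- pos[keep_cols]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(spos), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  hs <- haplotype_set("chr1", spos, ref, alt, S, sample_ids,
                      ancestral = "ref")
  sweep_deme_lab <- paste0("pop", sw$deme)
  groups <- stats::setNames(
    ifelse(paste0("pop", seq_len(nD)) == sweep_deme_lab, "hot", "cold"),
    paste0("pop", seq_len(nD)))
  popmap <- structure(list(assignments = assignments, groups = groups),
                      class = "PopulationMap")
  genmap <- genetic_map(list(chr1 = data.frame(bp = c(1, L),
                                               cm = c(1, L) * 1e-6)))
  final_deme <- if (sw$enabled && !is.na(sc))
    sum(H[deme_rows(sw$deme), sc]) / n2 else 0
  sample_variant <- if (sw$enabled) match(sw$position, spos) else NA_integer_
  final_sample <- if (!is.na(sample_variant)) {
    rows <- hap_rows(hs, names(assignments)[assignments == sweep_deme_lab])
    mean(hs$haplotypes[rows, sample_variant])
  } else if (sw$enabled) {
    if (final_deme > 0.5) 1 else 0   # fixed/lost among sampled haplotypes
  } else 0
  truth <- list(sweep_enabled = sw$enabled,
                position = if (sw$enabled) sw$position else NA_real_,
                final_freq_deme = final_deme,
                final_freq_sample = final_sample,
                trajectory = traj, attempts = attempts,
                sample_variant = sample_variant)
  list(haplotypes = hs, popmap = popmap, genmap = genmap, truth = truth,
       config = cfg)
}

#' Export a simulated dataset as standard files
#'
#' Writes a phased VCF, a three-column population map (with hot/cold
#' group labels), a PLINK-style `.map` genetic map (one line per variant)
#' and, when `genes` is given, a GFF3 annotation. Files round-trip
#' through the package readers.
#'
#' @param h A `HaplotypeSet`.
#' @param popmap A `PopulationMap`.
#' @param genmap Optional `GeneticMap` (default constant 1 cM/Mb).
#' @param genes Optional gene table ([random_genes()]).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"sim"`).
#' @return Named character vector of paths.
#' @export
export_dataset <- function(h, popmap, genmap = NULL, genes = NULL, dir,
                           prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             popmap = file.path(dir, paste0(prefix, ".popmap.txt")),
             map = file.path(dir, paste0(prefix, ".map")))
  write_phased_vcf(h, paths[["vcf"]])
  writeLines(paste(names(popmap$assignments), popmap$assignments,
                   popmap$groups[popmap$assignments], sep = "\t"),
             paths[["popmap"]])
  cm <- interpolate_cm(genmap, h$chrom, h$positions)
  writeLines(paste(h$chrom, paste0("snp", seq_len(n_variants(h))),
                   sprintf("%.8g", cm), h$positions, sep = "\t"),
             paths[["map"]])
  if (!is.null(genes)) {
    paths[["genes"]] <- file.path(dir, paste0(prefix, ".genes.gff3"))
    write_gff3(genes, paths[["genes"]])
  }
  paths
}

#' Generate a random gene annotation for simulation output
#'
#' Gene count ~ Poisson(density * length / 1 Mb); starts uniform, lengths
#' geometric with the given mean, all clipped to `[1, chrom_length]`.
#' Purely synthetic, for exercising gene-overlap annotation.
#'
#' @param chrom_length Chromosome length in bp.
#' @param density_per_mb Expected genes per Mb (default 10).
#' @param mean_length Mean gene length in bp (default 5000).
#' @param chrom Chromosome name.
#' @param seed Optional seed.
#' @return Gene table as from [read_gene_annotation()].
#' @export
random_genes <- function(chrom_length, density_per_mb = 10,
                         mean_length = 5000, chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, density_per_mb * chrom_length / 1e6)
  if (n == 0L)
    return(data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  start <- sort(sample.int(as.integer(chrom_length), n, replace = TRUE))
  len <- 1L + stats::rgeom(n, 1 / mean_length)
  end <- pmin(start + len - 1L, as.integer(chrom_length))
  data.frame(gene_id = sprintf("G%03d", seq_len(n)),
             gene_name = sprintf("gene%03d", seq_len(n)),
             chrom = chrom, start = start, end = end,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
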