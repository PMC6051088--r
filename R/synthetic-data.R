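#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators.  Defaults describe
#' a desk-scale cohort with the statistical structure the analysis assumes:
#' hairpin loci processed with Dicer-like 5' homogeneity, structureless decoy
#' loci, negative-binomial paired tumour/normal counts with planted fold
#' changes, exponential survival with a tertile-dependent hazard, and 3'UTRs
#' carrying exact complementary target sites.
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_true_hairpins Number of planted hairpin loci.
#' @param n_decoy_loci Number of structureless decoy (rRNA/tRNA) loci.
#' @param genome_length Genome size in bases; must be at least
#'   `10 * (n_true_hairpins + n_decoy_loci) * 120`.
#' @param read_depth_per_locus Reads per planted locus.
#' @param background_read_rate Background (degradation) reads per kilobase.
#' @param n_pairs Number of tumour/normal sample pairs (patients).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param planted_log2fc Per-hairpin tumour/normal log2 fold change, recycled
#'   across hairpin loci.
#' @param baseline_hazard Baseline death hazard, per day.
#' @param hazard_ratio_high_vs_low Hazard multiplier for patients in the top
#'   expression tertile of the designated survival loci.
#' @param n_survival_loci Number of hairpin loci whose expression carries the
#'   planted hazard ratio.
#' @param censor_rate Target fraction of censored patients, in `[0, 1]`.
#' @param n_utrs Number of synthetic 3'UTRs.
#' @param planted_sites_per_mirna Perfect complementary sites planted per
#'   miRNA.
#' @param n_target_pool Size of the shared pool of UTRs that target sites
#'   are drawn from; a pool smaller than `n_utrs` makes distinct miRNAs
#'   share target genes, as real miRNA families do, so the
#'   fraction-of-miRNAs aggregation rule has something to aggregate.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_true_hairpins = 30L,
                       n_decoy_loci = 20L,
                       genome_length = NULL,
                       read_depth_per_locus = 50L,
                       background_read_rate = 0.2,
                       n_pairs = 30L,
                       nb_dispersion = 0.1,
                       planted_log2fc = 0,
                       baseline_hazard = 1 / 1000,
                       hazard_ratio_high_vs_low = 3,
                       n_survival_loci = 2L,
                       censor_rate = 0.3,
                       n_utrs = 200L,
                       planted_sites_per_mirna = 1L,
                       n_target_pool = 30L) {
  if (is.null(genome_length)) {
    genome_length <- 10L * (n_true_hairpins + n_decoy_loci) * 120L + 10000L
  }
  cfg <- list(
    seed = as.integer(seed),
    n_true_hairpins = as.integer(n_true_hairpins),
    n_decoy_loci = as.integer(n_decoy_loci),
    genome_length = as.integer(genome_length),
    read_depth_per_locus = as.integer(read_depth_per_locus),
    background_read_rate = background_read_rate,
    n_pairs = as.integer(n_pairs),
    nb_dispersion = nb_dispersion,
    planted_log2fc = planted_log2fc,
    baseline_hazard = baseline_hazard,
    hazard_ratio_high_vs_low = hazard_ratio_high_vs_low,
    n_survival_loci = as.integer(n_survival_loci),
    censor_rate = censor_rate,
    n_utrs = as.integer(n_utrs),
    planted_sites_per_mirna = as.integer(planted_sites_per_mirna),
    n_target_pool = as.integer(min(n_target_pool, n_utrs))
  )
  counts <- c("n_true_hairpins", "n_decoy_loci", "read_depth_per_locus",
              "n_pairs", "n_utrs", "planted_sites_per_mirna",
              "n_survival_loci")
  for (nm in counts) {
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1) {
    stop("censor_rate must lie in [0, 1]")
  }
  if (cfg$background_read_rate < 0) stop("background_read_rate must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic genome with planted hairpins and decoys
#'
#' Plants `n_true_hairpins` inverted-repeat miRNA precursors (a 22-nt mature
#' arm, a 8-12 nt loop, and the mature arm's exact reverse complement, so the
#' stem carries 22 >= 18 pairings) and `n_decoy_loci` structureless decoy
#' intervals labelled rRNA/tRNA into a uniform random genome.  All truth
#' coordinates are 0-based half-open on chromosome `chr1`.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named character vector of chromosome
#'   sequences, DNA alphabet) and `truth`, a list with elements `hairpins`,
#'   `decoys`, `de_truth`, `survival_truth` and `target_truth`.
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_loci <- cfg$n_true_hairpins + cfg$n_decoy_loci
  if (n_loci > 0 && cfg$genome_length < 10L * n_loci * 120L) {
    stop("genome_length too small to pack ", n_loci,
         " loci: need >= ", 10L * n_loci * 120L, " bases")
  }
  .with_seed(cfg$seed, {
    bases <- c("A", "C", "G", "T")
    genome <- sample(bases, cfg$genome_length, replace = TRUE)

    # non-overlapping placement with a 60-bp margin between loci
    placed <- data.frame(start = integer(), end = integer())
    place <- function(len) {
      for (try in 1:2000) {
        s <- sample.int(cfg$genome_length - len - 1L, 1L)
        if (!any(s < placed$end + 60L & s + len + 60L > placed$start)) {
          placed[nrow(placed) + 1L, ] <<- c(s, s + len)
          return(s)
        }
      }
      stop("infeasible packing: could not place locus of length ", len,
           " in genome of length ", cfg$genome_length)
    }

    hairpins <- data.frame(
      id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), mature_start = integer(),
      mature_end = integer(), loop_len = integer(), mature_seq = character(),
      precursor_seq = character(), stringsAsFactors = FALSE
    )
    if (cfg$n_true_hairpins > 0) {
      for (i in seq_len(cfg$n_true_hairpins)) {
        mature_dna <- paste(sample(bases, 22L, replace = TRUE), collapse = "")
        loop_len <- sample(8:12, 1L)
        loop <- paste(sample(bases, loop_len, replace = TRUE), collapse = "")
        prec_dna <- paste0(mature_dna, loop, .revcomp_dna(mature_dna))
        len <- nchar(prec_dna)
        s <- place(len)
        genome[(s + 1L):(s + len)] <- strsplit(prec_dna, "")[[1]]
        hairpins[i, ] <- list(
          id = sprintf("hairpin_%03d", i), chrom = "chr1",
          start = s, end = s + len, strand = "+",
          mature_start = s, mature_end = s + 22L, loop_len = loop_len,
          mature_seq = .as_rna(mature_dna), precursor_seq = .as_rna(prec_dna)
        )
      }
    }

    decoys <- data.frame(
      id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), class = character(),
      stringsAsFactors = FALSE
    )
    if (cfg$n_decoy_loci > 0) {
      for (i in seq_len(cfg$n_decoy_loci)) {
        len <- sample(60:90, 1L)
        s <- place(len)
        decoys[i, ] <- list(
          id = sprintf("decoy_%03d", i), chrom = "chr1",
          start = s, end = s + len, strand = "+",
          class = if (i %% 2L == 1L) "rRNA" else "tRNA"
        )
      }
    }

    lfc <- rep_len(cfg$planted_log2fc, max(cfg$n_true_hairpins, 1L))
    de_truth <- data.frame(
      locus_id = hairpins$id,
      log2fc = if (nrow(hairpins)) lfc[seq_len(nrow(hairpins))] else numeric()
    )
    n_surv <- min(cfg$n_survival_loci, nrow(hairpins))
    survival_truth <- data.frame(
      locus_id = hairpins$id,
      hazard_ratio = rep(1, nrow(hairpins))
    )
    if (n_surv > 0) {
      survival_truth$hazard_ratio[seq_len(n_surv)] <-
        cfg$hazard_ratio_high_vs_low
    }

    list(
      genome = setNames(paste(genome, collapse = ""), "chr1"),
      truth = list(hairpins = hairpins, decoys = decoys, de_truth = de_truth,
                   survival_truth = survival_truth,
                   target_truth = data.frame(mirna_id = character(),
                                             gene_id = character()))
    )
  })
}

#' Simulate a read-placement table over a synthetic genome
#'
#' Each planted hairpin receives a Dicer-like stack: 85% of its reads start
#' exactly at the mature 5' end, a 10% minor stack sits on the star arm, and
#' the remaining reads carry 1-2 nt of 5' jitter, so the modal 5' end holds
#' >= 80% of locus reads.  Decoy loci receive the same depth as smeared reads
#' with heterogeneous 5' ends; background reads are placed by a Poisson
#' process at `background_read_rate` reads/kb.
#'
#' @param genome Named character vector from [generate_genome()].
#' @param truth Truth list from the same call.
#' @param cfg The same [sim_config()].
#' @return data.frame with columns read_id, chrom, start, end, strand, seq,
#'   sample (coordinates 0-based half-open).
#' @export
simulate_reads <- function(genome, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_expressed <- nrow(truth$hairpins) + nrow(truth$decoys)
  if (n_expressed > 0 && cfg$read_depth_per_locus <= 0) {
    stop("read_depth_per_locus must be > 0 when loci are planted")
  }
  .with_seed(cfg$seed + 1L, {
    chrom_seq <- genome[["chr1"]]
    glen <- nchar(chrom_seq)
    rows <- list()

    emit <- function(starts, lens, origin) {
      ends <- pmin(starts + lens, glen)
      data.frame(
        chrom = "chr1", start = starts, end = ends, strand = "+",
        seq = substring(chrom_seq, starts + 1L, ends),
        origin = origin
      )
    }

    for (i in seq_len(nrow(truth$hairpins))) {
      h <- truth$hairpins[i, ]
      d <- cfg$read_depth_per_locus
      n_mat <- round(0.85 * d)
      n_star <- round(0.10 * d)
      n_jit <- d - n_mat - n_star
      star_start <- h$mature_end + h$loop_len
      starts <- c(rep(h$mature_start, n_mat),
                  rep(star_start, n_star),
                  h$mature_start + sample(c(-2L, -1L, 1L, 2L), n_jit,
                                          replace = TRUE))
      lens <- 22L + sample(c(0L, 0L, 1L), length(starts), replace = TRUE)
      rows[[length(rows) + 1L]] <- emit(pmax(starts, 0L), lens, h$id)
    }

    for (i in seq_len(nrow(truth$decoys))) {
      dc <- truth$decoys[i, ]
      d <- cfg$read_depth_per_locus
      lens <- sample(18:30, d, replace = TRUE)
      starts <- dc$start +
        vapply(lens, function(l) {
          sample.int(max(dc$end - dc$start - l, 1L), 1L) - 1L
        }, integer(1))
      rows[[length(rows) + 1L]] <- emit(starts, lens, dc$id)
    }

    n_bg <- rpois(1L, cfg$background_read_rate * glen / 1000)
    if (n_bg > 0) {
      lens <- sample(18:30, n_bg, replace = TRUE)
      starts <- vapply(lens, function(l) {
        sample.int(glen - l, 1L) - 1L
      }, integer(1))
      rows[[length(rows) + 1L]] <- emit(starts, lens, "background")
    }

    reads <- if (length(rows)) do.call(rbind, rows) else
      emit(integer(), integer(), character())
    reads <- data.frame(
      read_id = sprintf("read_%06d", seq_len(nrow(reads))),
      reads[, c("chrom", "start", "end", "strand", "seq")],
      sample = "pooled", origin = reads$origin
    )
    reads$seq <- .as_dna(reads$seq)
    reads
  })
}

#' Simulate a paired tumour/normal cohort with survival outcomes
#'
#' Counts are negative binomial with per-locus baseline mean mu (log-normal
#' across loci) in normals and `mu * 2^planted_log2fc` in tumours, variance
#' `mu + dispersion * mu^2`.  Death times are exponential at
#' `baseline_hazard`, multiplied by `hazard_ratio_high_vs_low` for patients in
#' the top tumour-expression tertile of each designated survival locus;
#' censoring is administrative at the `1 - censor_rate` quantile of the
#' baseline time distribution.
#'
#' @param truth Truth list from [generate_genome()].
#' @param cfg The same [sim_config()]; needs `n_pairs >= 2`.
#' @return List with `counts` (loci x 2*n_pairs integer matrix; columns
#'   `<pair>_T` / `<pair>_N`) and `annotations` (sample, pair, condition,
#'   time_days, event).
#' @export
simulate_cohort <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_pairs < 2) stop("n_pairs must be >= 2")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  loci <- truth$de_truth$locus_id
  if (length(loci) == 0) stop("truth contains no hairpin loci to quantify")

  .with_seed(cfg$seed + 2L, {
    n <- length(loci)
    pairs <- sprintf("P%02d", seq_len(cfg$n_pairs))
    mu <- exp(rnorm(n, mean = log(200), sd = 0.8))
    size <- 1 / cfg$nb_dispersion
    lfc <- truth$de_truth$log2fc

    tum <- matrix(rnbinom(n * cfg$n_pairs, mu = rep(mu * 2^lfc, cfg$n_pairs),
                          size = size), nrow = n)
    nor <- matrix(rnbinom(n * cfg$n_pairs, mu = rep(mu, cfg$n_pairs),
                          size = size), nrow = n)
    counts <- matrix(0L, nrow = n, ncol = 2L * cfg$n_pairs)
    counts[, seq(1L, by = 2L, length.out = cfg$n_pairs)] <- tum
    counts[, seq(2L, by = 2L, length.out = cfg$n_pairs)] <- nor
    rownames(counts) <- loci
    colnames(counts) <- as.vector(rbind(paste0(pairs, "_T"),
                                        paste0(pairs, "_N")))

    # hazard driven by tumour-expression tertile of the designated loci
    hazard <- rep(cfg$baseline_hazard, cfg$n_pairs)
    surv_loci <- truth$survival_truth$locus_id[
      truth$survival_truth$hazard_ratio != 1]
    for (sl in surv_loci) {
      expr <- tum[match(sl, loci), ]
      q <- cfg$n_pairs %/% 3L
      if (q >= 1L && length(unique(expr)) > 1L) {
        top <- order(-expr, pairs)[seq_len(q)]
        hr <- truth$survival_truth$hazard_ratio[
          match(sl, truth$survival_truth$locus_id)]
        hazard[top] <- hazard[top] * hr
      }
    }
    death <- rexp(cfg$n_pairs, rate = hazard)
    horizon <- qexp(1 - cfg$censor_rate, rate = cfg$baseline_hazard)
    time <- pmin(death, horizon)
    event <- as.integer(death <= horizon)

    annotations <- data.frame(
      sample = colnames(counts),
      pair = rep(pairs, each = 2L),
      condition = rep(c("tumour", "normal"), cfg$n_pairs),
      time_days = rep(time, each = 2L),
      event = rep(event, each = 2L)
    )
    list(counts = counts, annotations = annotations)
  })
}

#' Plant perfect complementary target sites into synthetic 3'UTRs
#'
#' Generates `n_utrs` random RNA-alphabet UTRs (250-450 nt) and embeds, for
#' each miRNA, `planted_sites_per_mirna` exact reverse complements of the full
#' miRNA into distinct UTRs drawn from a shared pool of `n_target_pool`
#' genes (so different miRNAs can target the same gene, as miRNA families
#' do).  Sites within one UTR never overlap.  Non-target UTRs carry no
#' planted site.
#'
#' @param mirna_sequences Named character vector of mature miRNA sequences
#'   (RNA alphabet, 18-25 nt).
#' @param cfg A [sim_config()].
#' @return List with `utrs` (named character vector, RNA alphabet) and
#'   `target_truth` (mirna_id, gene_id, utr_start, utr_end; 0-based
#'   half-open).
#' @export
plant_target_sites <- function(mirna_sequences, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lens <- nchar(mirna_sequences)
  if (any(lens < 18 | lens > 25)) {
    stop("miRNA sequences must be 18-25 nt")
  }
  if (any(grepl("[^ACGU]", toupper(mirna_sequences)))) {
    stop("miRNA sequences must use the RNA alphabet (ACGU)")
  }
  .with_seed(cfg$seed + 3L, {
    bases <- c("A", "C", "G", "U")
    utr_len <- sample(250:450, cfg$n_utrs, replace = TRUE)
    utrs <- vapply(utr_len, function(l) {
      paste(sample(bases, l, replace = TRUE), collapse = "")
    }, character(1))
    names(utrs) <- sprintf("GENE%04d", seq_len(cfg$n_utrs))

    truth <- data.frame(mirna_id = character(), gene_id = character(),
                        utr_start = integer(), utr_end = integer())
    if (cfg$planted_sites_per_mirna > 0 && length(mirna_sequences) > 0) {
      if (cfg$planted_sites_per_mirna > cfg$n_target_pool) {
        stop("planted_sites_per_mirna exceeds the target gene pool (",
             cfg$n_target_pool, ")")
      }
      pool <- sample(names(utrs), cfg$n_target_pool)
      occupied <- lapply(setNames(vector("list", cfg$n_utrs), names(utrs)),
                         function(x) NULL)
      for (m in names(mirna_sequences)) {
        site <- .revcomp_rna(mirna_sequences[[m]])
        genes <- sample(pool, cfg$planted_sites_per_mirna)
        for (g in genes) {
          L <- nchar(utrs[[g]])
          if (L < nchar(site)) stop("UTR shorter than miRNA site")
          w <- nchar(site)
          pos <- NA_integer_
          for (try in 1:200) {
            cand <- sample.int(L - w + 1L, 1L)
            clash <- any(vapply(occupied[[g]], function(iv) {
              cand <= iv[2] && cand + w - 1L >= iv[1]
            }, logical(1)))
            if (!clash) { pos <- cand; break }
          }
          if (is.na(pos)) stop("could not place a non-overlapping site in ", g)
          substr(utrs[[g]], pos, pos + w - 1L) <- site
          occupied[[g]] <- c(occupied[[g]], list(c(pos, pos + w - 1L)))
          truth[nrow(truth) + 1L, ] <-
            list(m, g, pos - 1L, pos - 1L + w)
        }
      }
    }
    list(utrs = utrs, target_truth = truth)
  })
}

#' Build synthetic pathway gene sets around planted targets
#'
#' One pathway is enriched by construction (it contains the planted target
#' genes topped up with random genes); the remaining pathways are random draws
#' from the gene universe.
#'
#' @param gene_universe Character vector of all gene ids (e.g. UTR names).
#' @param target_genes Genes to concentrate in the enriched pathway.
#' @param n_pathways Total number of pathways.
#' @param pathway_size Genes per pathway.
#' @param seed Integer seed.
#' @return Named list of gene sets.
#' @export
simulate_pathways <- function(gene_universe, target_genes,
                              n_pathways = 20L, pathway_size = 25L,
                              seed = 1L) {
  .with_seed(seed, {
    target_genes <- intersect(target_genes, gene_universe)
    top_up <- sample(setdiff(gene_universe, target_genes),
                     max(pathway_size - length(target_genes), 0L))
    sets <- list(pathway_planted = c(target_genes, top_up))
    for (i in seq_len(n_pathways - 1L)) {
      sets[[sprintf("pathway_%02d", i)]] <-
        sample(gene_universe, min(pathway_size, length(gene_universe)))
    }
    sets
  })
}
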