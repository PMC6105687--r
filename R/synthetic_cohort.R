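#' Simulation configuration for a paired-timepoint synthetic cohort
#'
#' Defaults emulate the study design this package targets: ten patients, each
#' sampled at a smoldering (SMM) and a symptomatic (MM) timepoint, ~39x mean
#' depth, per-sample substitution totals in the observed whole-genome range,
#' a three-clone subclone tree (one clonal cluster, one disappearing and one
#' appearing subclone), clone-specific signature mixtures in which
#' noncanonical AID dominates early (clonal) mutations while APOBEC and a
#' broad C>A process dominate late ones, a median of six kataegis regions per
#' patient (the first three planted in toy immunoglobulin loci with a
#' canonical-AID-heavy spectrum), and ~35 rearrangements per patient of which
#' 60% fall near a kataegis region (breakpoint offset exponential, mean
#' 10 kb).
#'
#' The toy reference genome is generated i.i.d. uniform over A/C/G/T per
#' chromosome from the seed, which guarantees all 32 pyrimidine-centred
#' trinucleotide contexts occur at usable density. Simulated mutations carry
#' multiplicity 1.
#'
#' @param seed integer master seed.
#' @param n_patients number of patients (each with two timepoints).
#' @param chromosome_lengths named vector of toy chromosome lengths (bp);
#'   every chromosome must be at least `10 * kataegis_span` long.
#' @param purity_range interval in (0, 1] from which per-sample purity is
#'   drawn.
#' @param depth mean sequencing depth (per-site totals are Poisson).
#' @param n_mutations_range integer interval for per-patient mutation totals.
#' @param subclone_tree data.frame with `clone`, `ccf_smm`, `ccf_mm`,
#'   `mutation_fraction` (fractions sum to 1).
#' @param signature_mixtures clones x processes matrix of per-clone mixture
#'   weights (rows sum to 1); column names must name rows of
#'   `reference_signatures`.
#' @param mixture_concentration Dirichlet concentration for per-patient
#'   variation around each clone's configured mixture (the realized mixture
#'   of patient p is `Dirichlet(concentration * mixture)`); process
#'   contributions vary severalfold between patients of one cohort, and the
#'   default (10) reproduces spreads of that order. `Inf` disables the
#'   variation. Realized per-patient mixtures are recorded in the ground
#'   truth.
#' @param reference_signatures catalog the mixtures refer to; defaults to
#'   [bundled_signatures()] with the canonical-AID process included.
#' @param n_kataegis kataegis regions per patient.
#' @param kataegis_span width of each planted region (bp).
#' @param kataegis_n_mutations mutations planted per region (must be at least
#'   the detection minimum you intend to use).
#' @param kataegis_mixture,ig_kataegis_mixture named mixture vectors for
#'   non-IG and IG kataegis mutations.
#' @param ig_intervals toy immunoglobulin loci (data.frame `locus`, `chrom`,
#'   `start`, `end`) used for IG kataegis placement; up to three regions per
#'   patient are planted inside them.
#' @param n_rearrangements rearrangements per patient.
#' @param fraction_rearrangements_near_kataegis fraction with a breakpoint
#'   planted near a kataegis region.
#' @param rearrangement_proximity_mean mean of the exponential breakpoint
#'   offset for "near kataegis" placement (bp).
#' @param cn_events optional data.frame (`chrom`, `start`, `end`, `major`,
#'   `minor`) of non-diploid segments applied to every patient; the rest of
#'   the genome stays 1+1.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1,
    n_patients = 10,
    chromosome_lengths = c(`1` = 25e6, `2` = 25e6, `3` = 25e6, `4` = 25e6),
    purity_range = c(0.7, 0.95),
    depth = 38.7,
    n_mutations_range = c(2400L, 7300L),
    subclone_tree = data.frame(
      clone = c("clonal", "disappearing", "appearing"),
      ccf_smm = c(1.0, 0.5, 0.0),
      ccf_mm = c(1.0, 0.0, 0.6),
      mutation_fraction = c(0.5, 0.25, 0.25)),
    signature_mixtures = rbind(
      clonal = c(age_related = 0.20, apobec = 0.05, nc_aid = 0.47,
                 sig8_like = 0.21, mm1_like = 0.07),
      disappearing = c(age_related = 0.20, apobec = 0.27, nc_aid = 0.05,
                       sig8_like = 0.36, mm1_like = 0.12),
      appearing = c(age_related = 0.18, apobec = 0.30, nc_aid = 0.02,
                    sig8_like = 0.40, mm1_like = 0.10)),
    reference_signatures = bundled_signatures(include_caid = TRUE),
    mixture_concentration = 10,
    n_kataegis = 6,
    kataegis_span = 1000,
    kataegis_n_mutations = 8,
    kataegis_mixture = c(apobec = 0.45, nc_aid = 0.30, c_aid = 0.25),
    ig_kataegis_mixture = c(c_aid = 0.60, nc_aid = 0.20, apobec = 0.20),
    ig_intervals = data.frame(
      locus = c("IGH_toy", "IGK_toy", "IGL_toy"),
      chrom = c("1", "2", "3"),
      start = c(1000001L, 2000001L, 3000001L),
      end = c(1050000L, 2050000L, 3050000L)),
    n_rearrangements = 35,
    fraction_rearrangements_near_kataegis = 0.6,
    rearrangement_proximity_mean = 10000,
    cn_events = NULL) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              chromosome_lengths = chromosome_lengths,
              purity_range = purity_range, depth = depth,
              n_mutations_range = as.integer(n_mutations_range),
              subclone_tree = subclone_tree,
              signature_mixtures = signature_mixtures,
              reference_signatures = reference_signatures,
              mixture_concentration = mixture_concentration,
              n_kataegis = as.integer(n_kataegis),
              kataegis_span = as.integer(kataegis_span),
              kataegis_n_mutations = as.integer(kataegis_n_mutations),
              kataegis_mixture = kataegis_mixture,
              ig_kataegis_mixture = ig_kataegis_mixture,
              ig_intervals = ig_intervals,
              n_rearrangements = as.integer(n_rearrangements),
              fraction_rearrangements_near_kataegis =
                fraction_rearrangements_near_kataegis,
              rearrangement_proximity_mean = rearrangement_proximity_mean,
              cn_events = cn_events)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  st <- cfg$subclone_tree
  if (abs(sum(st$mutation_fraction) - 1) > 1e-9) {
    stop("configuration error: clone mutation fractions must sum to 1")
  }
  if (any(st$ccf_smm < 0 | st$ccf_smm > 1 | st$ccf_mm < 0 | st$ccf_mm > 1)) {
    stop("configuration error: clone CCFs must lie in [0, 1]")
  }
  mix <- cfg$signature_mixtures
  if (nrow(mix) != nrow(st)) {
    stop("configuration error: one signature mixture per clone is required")
  }
  procs <- rownames(cfg$reference_signatures)
  check_mix <- function(v, what) {
    unknown <- setdiff(names(v), procs)
    if (length(unknown)) {
      stop("configuration error: ", what, " references unknown process(es): ",
           paste(unknown, collapse = ", "))
    }
    if (abs(sum(v) - 1) > 1e-9) {
      stop("configuration error: ", what, " must sum to 1")
    }
  }
  for (i in seq_len(nrow(mix))) {
    v <- setNames(as.numeric(mix[i, ]), colnames(mix))
    check_mix(v, paste0("signature mixture for clone '", st$clone[i], "'"))
  }
  check_mix(cfg$kataegis_mixture, "kataegis mixture")
  check_mix(cfg$ig_kataegis_mixture, "IG kataegis mixture")
  if (any(cfg$purity_range <= 0 | cfg$purity_range > 1)) {
    stop("configuration error: purity range must lie in (0, 1]")
  }
  if (!is.null(cfg$mixture_concentration) && cfg$mixture_concentration <= 0) {
    stop("configuration error: mixture_concentration must be positive")
  }
  if (any(cfg$chromosome_lengths < 10 * cfg$kataegis_span)) {
    stop("configuration error: every chromosome must be at least 10x the kataegis span")
  }
  if (cfg$fraction_rearrangements_near_kataegis < 0 ||
      cfg$fraction_rearrangements_near_kataegis > 1) {
    stop("configuration error: fraction_rearrangements_near_kataegis must lie in [0, 1]")
  }
  ig <- cfg$ig_intervals
  if (!is.null(ig) && nrow(ig) > 0 && cfg$n_kataegis > 0) {
    ch <- normalize_chrom(ig$chrom)
    unknown <- setdiff(ch, names(cfg$chromosome_lengths))
    if (length(unknown)) {
      stop("configuration error: IG interval on unknown chromosome ",
           paste(unknown, collapse = ", "))
    }
    bad <- ig$start < 1 | ig$end > cfg$chromosome_lengths[ch]
    if (any(bad)) {
      stop("configuration error: IG interval outside chromosome ",
           ch[which(bad)[1]])
    }
  }
  invisible(cfg)
}

random_genome <- function(chromosome_lengths) {
  cp <- utf8ToInt("ACGT")
  seqs <- lapply(chromosome_lengths, function(L) {
    intToUtf8(cp[sample.int(4L, L, replace = TRUE)])
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs, use.names = FALSE))
  names(genome) <- names(chromosome_lengths)
  genome
}

parse_class <- function(label) {
  data.frame(p5 = substr(label, 1, 1), ref = substr(label, 3, 3),
             alt = substr(label, 5, 5), p3 = substr(label, 7, 7),
             ctx = paste0(substr(label, 1, 1), substr(label, 3, 3),
                          substr(label, 7, 7)))
}

strand_normalize_tri <- function(tri) {
  centre <- substr(tri, 2, 2)
  flip <- centre %in% c("A", "G")
  tri[flip] <- reverse_complement(tri[flip])
  tri
}

# place mutations with required pyrimidine-context trinucleotides on one
# chromosome by vectorized rejection sampling; returns positions aligned to ctx
place_on_chromosome <- function(seq, ch, ctx, taken = integer(0)) {
  n <- length(ctx)
  L <- length(seq)
  res <- rep(NA_integer_, n)
  tries <- 0
  while (anyNA(res)) {
    tries <- tries + 1
    if (tries > 60) {
      stop("generation error: chromosome ", ch,
           " is too short to place the requested trinucleotide contexts")
    }
    rem <- which(is.na(res))
    n_cand <- min(200L * length(rem) + 200L, 5000000L)
    cand <- unique(2L + floor(runif(n_cand) * (L - 2L)))
    cand <- cand[!(cand %in% taken)]
    if (length(cand) == 0) next
    tri <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(start = cand - 1L, width = 3L)))
    norm <- strand_normalize_tri(tri)
    avail <- split(cand, norm)
    for (cc in unique(ctx[rem])) {
      pool <- avail[[cc]]
      if (is.null(pool)) next
      want <- rem[ctx[rem] == cc]
      take <- min(length(pool), length(want))
      if (take > 0) {
        res[want[seq_len(take)]] <- pool[seq_len(take)]
        taken <- c(taken, pool[seq_len(take)])
      }
    }
  }
  res
}

# all positions inside [start, end] (1-based) whose strand-normalized
# trinucleotide matches each required context
place_in_interval <- function(seq, ch, start, end, ctx) {
  lo <- max(2L, start)
  hi <- min(length(seq) - 1L, end)
  pos <- lo:hi
  tri <- as.character(Biostrings::extractAt(
    seq, IRanges::IRanges(start = pos - 1L, width = 3L)))
  norm <- strand_normalize_tri(tri)
  res <- rep(NA_integer_, length(ctx))
  used <- logical(length(pos))
  for (i in seq_along(ctx)) {
    ok <- which(norm == ctx[i] & !used)
    if (length(ok) == 0) {
      stop("generation error: chromosome ", ch, " interval ", start, "-", end,
           " lacks context ", ctx[i])
    }
    pick <- ok[sample.int(length(ok), 1)]
    used[pick] <- TRUE
    res[i] <- pos[pick]
  }
  res
}

default_segments <- function(cfg) {
  base <- data.frame(chrom = names(cfg$chromosome_lengths), start = 1L,
                     end = as.integer(cfg$chromosome_lengths),
                     major = 1L, minor = 1L)
  ev <- cfg$cn_events
  if (is.null(ev) || nrow(ev) == 0) return(base)
  out <- list()
  for (ch in base$chrom) {
    L <- base$end[base$chrom == ch]
    e <- ev[normalize_chrom(ev$chrom) == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    cur <- 1L
    for (q in seq_len(nrow(e))) {
      if (e$start[q] > cur) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur,
                                             end = e$start[q] - 1L,
                                             major = 1L, minor = 1L)
      }
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = e$start[q],
                                           end = e$end[q],
                                           major = e$major[q],
                                           minor = e$minor[q])
      cur <- e$end[q] + 1L
    }
    if (cur <= L) {
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur, end = L,
                                           major = 1L, minor = 1L)
    }
  }
  do.call(rbind, out)
}

draw_counts <- function(n, depth, p) {
  total <- rpois(n, depth)
  alt <- rbinom(n, total, pmin(pmax(p, 0), 1))
  list(total = total, alt = alt)
}

#' Generate a paired-timepoint cohort with planted ground truth
#'
#' Runs the full generative model described in [simulation_config()]: a seeded
#' toy genome, per-patient mutations placed at positions whose reference
#' trinucleotide realizes the class drawn from the mutation's clone-specific
#' signature mixture, planted kataegis regions, rearrangements (a configured
#' fraction near kataegis), diploid-plus-events copy-number segments and
#' per-sample purities. Alt read counts at each timepoint are binomial with
#' success probability equal to the expected VAF given the clone CCF, purity,
#' local copy number and multiplicity 1; totals are Poisson at the configured
#' mean depth. Outputs are deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `cohort` (genome, mutations, rearrangements, segments,
#'   purity, config) and `truth` (per-mutation clone labels, clone CCFs,
#'   mixtures, planted kataegis intervals, rearrangement clone fractions).
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  cfg <- config
  genome <- random_genome(cfg$chromosome_lengths)
  chroms <- names(cfg$chromosome_lengths)
  lens <- cfg$chromosome_lengths
  st <- cfg$subclone_tree
  segments <- default_segments(cfg)
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))

  purity <- data.frame(
    patient = rep(patients, each = 2),
    timepoint = rep(.tp_levels, cfg$n_patients),
    acf = runif(2 * cfg$n_patients, cfg$purity_range[1], cfg$purity_range[2]))

  mut_list <- list(); rr_list <- list(); kat_list <- list()
  clone_labels <- list(); rr_truth <- list(); patient_mixtures <- list()

  ref_sigs <- cfg$reference_signatures
  classes <- context_classes()

  for (pt in patients) {
    rho <- setNames(purity$acf[purity$patient == pt],
                    purity$timepoint[purity$patient == pt])

    ## per-patient realized signature mixtures: Dirichlet around the
    ## configured clone mixtures (zero-weight processes stay zero), giving
    ## the between-patient exposure variation real cohorts show
    mix_pt <- cfg$signature_mixtures
    if (is.finite(cfg$mixture_concentration)) {
      for (ci in seq_len(nrow(mix_pt))) {
        gam <- rgamma(ncol(mix_pt),
                      shape = cfg$mixture_concentration *
                        as.numeric(cfg$signature_mixtures[ci, ]))
        if (sum(gam) > 0) mix_pt[ci, ] <- gam / sum(gam)
      }
    }
    patient_mixtures[[pt]] <- mix_pt

    ## ---- kataegis intervals (disjoint per chromosome) ----
    kat <- NULL
    if (cfg$n_kataegis > 0) {
      n_ig <- min(nrow(cfg$ig_intervals), cfg$n_kataegis)
      rows <- list()
      for (q in seq_len(cfg$n_kataegis)) {
        ok <- FALSE
        for (attempt in 1:100) {
          if (q <= n_ig) {
            ig <- cfg$ig_intervals[q, ]
            ch <- normalize_chrom(ig$chrom)
            s <- ig$start + floor(runif(1) * max(1, ig$end - ig$start - cfg$kataegis_span))
          } else {
            ch <- chroms[sample.int(length(chroms), 1)]
            s <- 2L + floor(runif(1) * (lens[[ch]] - cfg$kataegis_span - 4L))
          }
          e <- s + cfg$kataegis_span - 1L
          clash <- FALSE
          for (r in rows) {
            if (r$chrom == ch && s <= r$end && e >= r$start) clash <- TRUE
          }
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) stop("generation error: cannot place disjoint kataegis intervals on chromosome ", ch)
        rows[[q]] <- data.frame(patient = pt, chrom = ch, start = as.integer(s),
                                end = as.integer(e), is_ig = q <= n_ig)
      }
      kat <- do.call(rbind, rows)
      kat_list[[pt]] <- kat
    }

    ## ---- kataegis mutations (planted in the clonal clone) ----
    kat_chrom <- character(0); kat_pos <- integer(0); kat_pc <- NULL
    if (!is.null(kat)) {
      kat$process <- NA_character_
      for (q in seq_len(nrow(kat))) {
        mixture <- if (kat$is_ig[q]) cfg$ig_kataegis_mixture else cfg$kataegis_mixture
        # one enzymatic storm per region: a single process drives all of a
        # region's mutations, drawn from the configured mixture
        kproc <- sample(names(mixture), 1, prob = mixture)
        kat$process[q] <- kproc
        klab <- sample(classes, cfg$kataegis_n_mutations, replace = TRUE,
                       prob = ref_sigs[kproc, ])
        kpc <- parse_class(klab)
        kpos <- place_in_interval(genome[[kat$chrom[q]]], kat$chrom[q],
                                  kat$start[q], kat$end[q], kpc$ctx)
        kat_chrom <- c(kat_chrom, rep(kat$chrom[q], cfg$kataegis_n_mutations))
        kat_pos <- c(kat_pos, kpos)
        kat_pc <- if (is.null(kat_pc)) kpc else rbind(kat_pc, kpc)
      }
      kat_list[[pt]] <- kat
    }

    ## ---- background mutations ----
    n_mut <- cfg$n_mutations_range[1] +
      floor(runif(1) * (cfg$n_mutations_range[2] - cfg$n_mutations_range[1] + 1))
    clone_idx <- sample.int(nrow(st), n_mut, replace = TRUE,
                            prob = st$mutation_fraction)
    proc <- character(n_mut)
    for (ci in seq_len(nrow(st))) {
      sel <- clone_idx == ci
      if (!any(sel)) next
      mixture <- setNames(as.numeric(mix_pt[ci, ]), colnames(mix_pt))
      proc[sel] <- sample(names(mixture), sum(sel), replace = TRUE,
                          prob = mixture)
    }
    class_lab <- character(n_mut)
    for (pr in unique(proc)) {
      sel <- proc == pr
      class_lab[sel] <- sample(classes, sum(sel), replace = TRUE,
                               prob = ref_sigs[pr, ])
    }
    mut_chrom <- chroms[sample.int(length(chroms), n_mut, replace = TRUE,
                                   prob = lens / sum(lens))]
    pc <- parse_class(class_lab)
    pos <- integer(n_mut)
    for (ch in chroms) {
      sel <- which(mut_chrom == ch)
      if (length(sel) == 0) next
      pos[sel] <- place_on_chromosome(genome[[ch]], ch, pc$ctx[sel],
                                      taken = kat_pos[kat_chrom == ch])
    }

    ## ---- combine background and kataegis mutations ----
    if (length(kat_pos)) {
      mut_chrom <- c(mut_chrom, kat_chrom)
      pos <- c(pos, kat_pos)
      pc <- rbind(pc, kat_pc)
      clone_idx <- c(clone_idx, rep(1L, length(kat_pos)))
    }

    ## ---- alleles on the forward strand ----
    n_all <- length(pos)
    tri <- character(n_all)
    for (ch in chroms) {
      sel <- which(mut_chrom == ch)
      if (length(sel) == 0) next
      tri[sel] <- as.character(Biostrings::extractAt(
        genome[[ch]], IRanges::IRanges(start = pos[sel] - 1L, width = 3L)))
    }
    centre <- substr(tri, 2, 2)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    flip <- centre %in% c("A", "G")
    ref_allele <- ifelse(flip, comp[pc$ref], pc$ref)
    alt_allele <- ifelse(flip, comp[pc$alt], pc$alt)

    ## ---- read counts ----
    hit <- match_segment(mut_chrom, pos, segments)
    cnt <- segments$major[hit] + segments$minor[hit]
    ccf_smm <- st$ccf_smm[clone_idx]
    ccf_mm <- st$ccf_mm[clone_idx]
    p_smm <- ccf_smm * expected_vaf(rho[["SMM"]], cnt, 1)
    p_mm <- ccf_mm * expected_vaf(rho[["MM"]], cnt, 1)
    c_smm <- draw_counts(n_all, cfg$depth, p_smm)
    c_mm <- draw_counts(n_all, cfg$depth, p_mm)

    mut_list[[pt]] <- data.frame(
      patient = rep(pt, n_all), chrom = mut_chrom, pos = pos,
      ref = unname(ref_allele), alt = unname(alt_allele),
      ref_count_smm = c_smm$total - c_smm$alt, alt_count_smm = c_smm$alt,
      ref_count_mm = c_mm$total - c_mm$alt, alt_count_mm = c_mm$alt)
    clone_labels[[pt]] <- st$clone[clone_idx]

    ## ---- rearrangements ----
    if (cfg$n_rearrangements > 0) {
      nr <- cfg$n_rearrangements
      r_clone <- sample.int(nrow(st), nr, replace = TRUE,
                            prob = st$mutation_fraction)
      types <- c("deletion", "inversion", "tandem_duplication", "translocation")
      sv_type <- types[sample.int(4, nr, replace = TRUE)]
      near <- runif(nr) < cfg$fraction_rearrangements_near_kataegis &
        !is.null(kat)
      chrom1 <- character(nr); pos1 <- integer(nr)
      chrom2 <- character(nr); pos2 <- integer(nr)
      for (q in seq_len(nr)) {
        if (near[q] && !is.null(kat) && nrow(kat) > 0) {
          kq <- sample.int(nrow(kat), 1)
          off <- ceiling(rexp(1, 1 / cfg$rearrangement_proximity_mean))
          side <- sample(c(-1, 1), 1)
          chrom1[q] <- kat$chrom[kq]
          pos1[q] <- min(max(2L, if (side > 0) kat$end[kq] + off else kat$start[kq] - off),
                         lens[[chrom1[q]]] - 1L)
        } else {
          chrom1[q] <- chroms[sample.int(length(chroms), 1)]
          pos1[q] <- 2L + floor(runif(1) * (lens[[chrom1[q]]] - 2L))
        }
        if (sv_type[q] == "translocation") {
          others <- setdiff(chroms, chrom1[q])
          chrom2[q] <- others[sample.int(length(others), 1)]
          pos2[q] <- 2L + floor(runif(1) * (lens[[chrom2[q]]] - 2L))
        } else {
          chrom2[q] <- chrom1[q]
          size <- 10000L + floor(runif(1) * 990000L)
          pos2[q] <- min(pos1[q] + size, lens[[chrom2[q]]] - 1L)
        }
      }
      strands <- list(deletion = c("+", "-"),
                      tandem_duplication = c("-", "+"),
                      inversion = c("+", "+"),
                      translocation = c("+", "-"))
      strand1 <- vapply(sv_type, function(t) strands[[t]][1], character(1))
      strand2 <- vapply(sv_type, function(t) strands[[t]][2], character(1))
      hit1 <- match_segment(chrom1, pos1, segments)
      hit2 <- match_segment(chrom2, pos2, segments)
      cn_bar <- (segments$major[hit1] + segments$minor[hit1] +
                   segments$major[hit2] + segments$minor[hit2]) / 2
      f_smm <- st$ccf_smm[r_clone]
      f_mm <- st$ccf_mm[r_clone]
      raw_smm <- f_smm * rho[["SMM"]] /
        (rho[["SMM"]] * cn_bar + (1 - rho[["SMM"]]) * 2)
      raw_mm <- f_mm * rho[["MM"]] /
        (rho[["MM"]] * cn_bar + (1 - rho[["MM"]]) * 2)
      r_smm <- draw_counts(nr, cfg$depth, raw_smm)
      r_mm <- draw_counts(nr, cfg$depth, raw_mm)
      # a breakpoint needs at least one covering read to be reported
      r_smm$total <- pmax(r_smm$total, 1L)
      r_mm$total <- pmax(r_mm$total, 1L)
      rr_list[[pt]] <- data.frame(
        patient = pt, chrom1 = chrom1, pos1 = pos1, strand1 = unname(strand1),
        chrom2 = chrom2, pos2 = pos2, strand2 = unname(strand2),
        sv_type = sv_type,
        support_smm = r_smm$alt, total_smm = r_smm$total,
        support_mm = r_mm$alt, total_mm = r_mm$total)
      rr_truth[[pt]] <- data.frame(patient = pt, index = seq_len(nr),
                                   clone = st$clone[r_clone],
                                   fraction_smm = f_smm, fraction_mm = f_mm,
                                   near_kataegis = near)
    }
  }

  seg_all <- do.call(rbind, lapply(patients, function(pt) {
    cbind(patient = pt, segments)
  }))
  cohort <- list(
    genome = genome,
    patients = patients,
    mutations = do.call(rbind, mut_list),
    rearrangements = if (length(rr_list)) do.call(rbind, rr_list) else NULL,
    segments = seg_all,
    purity = purity,
    config = cfg)
  rownames(cohort$mutations) <- NULL
  if (!is.null(cohort$rearrangements)) rownames(cohort$rearrangements) <- NULL
  truth <- list(
    clone_labels = clone_labels,
    clone_ccfs = st,
    signature_mixtures = cfg$signature_mixtures,
    patient_mixtures = patient_mixtures,
    kataegis = if (length(kat_list)) {
      k <- do.call(rbind, kat_list); rownames(k) <- NULL; k
    } else NULL,
    rearrangement_fractions = if (length(rr_truth)) {
      r <- do.call(rbind, rr_truth); rownames(r) <- NULL; r
    } else NULL)
  list(cohort = cohort, truth = truth)
}

#' Write a synthetic cohort to disk as standard formats
#'
#' Per patient and timepoint: a VCF of substitutions (ref/alt depths in the
#' `AD` FORMAT field), a BEDPE of rearrangements (supporting/total read
#' counts in columns 11-12), and a copy-number segment TSV; plus one cohort
#' purity TSV, the toy reference FASTA and a `manifest.tsv` that
#' [run_pipeline()] and [read_cohort()] consume.
#'
#' @param generated output of [generate_cohort()] (the `cohort` element is
#'   also accepted directly).
#' @param dir output directory (created if needed).
#' @return data.frame manifest of every written file with record counts.
#' @export
write_fixture <- function(generated, dir) {
  cohort <- if (!is.null(generated$cohort)) generated$cohort else generated
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory ", dir)
  }
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  contigs <- setNames(Biostrings::width(cohort$genome), names(cohort$genome))
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(cohort$genome, fa)
  files <- data.frame(file = "genome.fa", type = "fasta",
                      n_records = length(cohort$genome))

  pur <- data.frame(sample_id = cohort$purity$patient,
                    timepoint = cohort$purity$timepoint,
                    acf = cohort$purity$acf)
  pur_path <- file.path(dir, "purity.tsv")
  data.table::fwrite(pur, pur_path, sep = "\t")
  files <- rbind(files, data.frame(file = "purity.tsv", type = "purity",
                                   n_records = nrow(pur)))

  manifest <- list()
  for (pt in cohort$patients) {
    mut <- cohort$mutations[cohort$mutations$patient == pt, , drop = FALSE]
    rr <- if (!is.null(cohort$rearrangements)) {
      cohort$rearrangements[cohort$rearrangements$patient == pt, , drop = FALSE]
    } else NULL
    seg <- cohort$segments[cohort$segments$patient == pt, , drop = FALSE]
    for (tp in .tp_levels) {
      suf <- tolower(tp)
      vcf_name <- sprintf("%s_%s.vcf", pt, suf)
      m <- data.frame(chrom = mut$chrom, pos = mut$pos, ref = mut$ref,
                      alt = mut$alt,
                      ref_count = mut[[paste0("ref_count_", suf)]],
                      alt_count = mut[[paste0("alt_count_", suf)]])
      write_vcf(m, file.path(dir, vcf_name), paste0(pt, "_", tp), contigs)
      files <- rbind(files, data.frame(file = vcf_name, type = "vcf",
                                       n_records = nrow(m)))
      bedpe_name <- sprintf("%s_%s.bedpe", pt, suf)
      r <- if (!is.null(rr) && nrow(rr) > 0) {
        data.frame(chrom1 = rr$chrom1, pos1 = rr$pos1, strand1 = rr$strand1,
                   chrom2 = rr$chrom2, pos2 = rr$pos2, strand2 = rr$strand2,
                   sv_type = rr$sv_type,
                   support_reads = rr[[paste0("support_", suf)]],
                   total_reads = rr[[paste0("total_", suf)]])
      } else {
        data.frame(chrom1 = character(0), pos1 = integer(0),
                   strand1 = character(0), chrom2 = character(0),
                   pos2 = integer(0), strand2 = character(0),
                   sv_type = character(0), support_reads = integer(0),
                   total_reads = integer(0))
      }
      write_bedpe(r, file.path(dir, bedpe_name))
      files <- rbind(files, data.frame(file = bedpe_name, type = "bedpe",
                                       n_records = nrow(r)))
      seg_name <- sprintf("%s_%s.segments.tsv", pt, suf)
      write_segments(seg, file.path(dir, seg_name))
      files <- rbind(files, data.frame(file = seg_name, type = "segments",
                                       n_records = nrow(seg)))
      manifest[[length(manifest) + 1]] <- data.frame(
        patient = pt, timepoint = tp, vcf = vcf_name, bedpe = bedpe_name,
        segments = seg_name, purity = "purity.tsv", fasta = "genome.fa")
    }
  }
  manifest <- do.call(rbind, manifest)
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  files <- rbind(files, data.frame(file = "manifest.tsv", type = "manifest",
                                   n_records = nrow(manifest)))
  rownames(files) <- NULL
  files
}

#' Read a cohort fixture back from disk
#'
#' Inverse of [write_fixture()]: reconstructs the wide per-patient mutation
#' and rearrangement tables by joining the two timepoints on their defining
#' coordinates.
#'
#' @param dir directory containing `manifest.tsv` and the files it lists.
#' @return list shaped like the `cohort` element of [generate_cohort()]
#'   (without the config).
#' @export
read_cohort <- function(dir) {
  manifest <- data.table::fread(file.path(dir, "manifest.tsv"),
                                data.table = FALSE)
  genome <- Biostrings::readDNAStringSet(file.path(dir, manifest$fasta[1]))
  names(genome) <- sub("\\s.*$", "", names(genome))
  purity_raw <- read_purity(file.path(dir, manifest$purity[1]))
  purity <- data.frame(patient = purity_raw$sample_id,
                       timepoint = purity_raw$timepoint, acf = purity_raw$acf)
  patients <- unique(manifest$patient)
  mut_list <- list(); rr_list <- list(); seg_list <- list()
  for (pt in patients) {
    rows <- manifest[manifest$patient == pt, , drop = FALSE]
    per_tp <- list()
    rr_tp <- list()
    for (q in seq_len(nrow(rows))) {
      tp <- rows$timepoint[q]
      per_tp[[tp]] <- suppressMessages(
        read_mutations(file.path(dir, rows$vcf[q]), pt, tp))
      rr_tp[[tp]] <- read_rearrangements(file.path(dir, rows$bedpe[q]), pt, tp)
      if (tp == "SMM") {
        seg <- read_segments(file.path(dir, rows$segments[q]), pt, tp)
        seg_list[[pt]] <- cbind(patient = pt,
                                seg[, c("chrom", "start", "end", "major", "minor")])
      }
    }
    key <- c("chrom", "pos", "ref", "alt")
    m <- merge(per_tp$SMM[, c(key, "ref_count", "alt_count")],
               per_tp$MM[, c(key, "ref_count", "alt_count")],
               by = key, all = TRUE, suffixes = c("_smm", "_mm"))
    m <- m[order(m$chrom, m$pos), , drop = FALSE]
    mut_list[[pt]] <- cbind(patient = pt, m)
    rkey <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2", "sv_type")
    r <- merge(rr_tp$SMM[, c(rkey, "support_reads", "total_reads")],
               rr_tp$MM[, c(rkey, "support_reads", "total_reads")],
               by = rkey, all = TRUE, suffixes = c("_smm", "_mm"))
    if (nrow(r) > 0) {
      names(r)[names(r) == "support_reads_smm"] <- "support_smm"
      names(r)[names(r) == "total_reads_smm"] <- "total_smm"
      names(r)[names(r) == "support_reads_mm"] <- "support_mm"
      names(r)[names(r) == "total_reads_mm"] <- "total_mm"
      r <- r[order(r$chrom1, r$pos1, r$chrom2, r$pos2), , drop = FALSE]
      rr_list[[pt]] <- cbind(patient = pt, r)
    }
  }
  mutations <- do.call(rbind, mut_list)
  rownames(mutations) <- NULL
  rearrangements <- if (length(rr_list)) do.call(rbind, rr_list) else NULL
  if (!is.null(rearrangements)) rownames(rearrangements) <- NULL
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  list(genome = genome, patients = patients, mutations = mutations,
       rearrangements = rearrangements, segments = segments, purity = purity)
}
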