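#' Simulation parameters for the two-population Wright-Fisher model
#'
#' Desk-scale defaults: diploid population sizes of 200, a 500-kb
#' chromosome, and per-bp mutation and crossover probabilities scaled up
#' to 2.5e-7 so that roughly 1-3 SNPs/kb segregate (population-scaled
#' theta = 4 N mu L = 100). These are scaled parameters chosen for
#' tractable simulation, not biological estimates. Sample sizes default to
#' 8 and 6 diploids, the size of a typical small re-sequencing contrast of
#' two breeds. The ancestral population is coalescent-seeded and then
#' equilibrated forward for `burn_in` generations so that recombination
#' shapes short-range LD before the split.
#'
#' @param N_anc,N_A,N_B diploid population sizes.
#' @param t_split generations of independent evolution since the split.
#' @param L chromosome length in bp.
#' @param mu per-bp per-generation mutation probability.
#' @param rho per-bp per-generation crossover probability.
#' @param n_sample_A,n_sample_B diploids sampled from each population.
#' @param burn_in forward equilibration generations after coalescent
#'   seeding.
#' @param seed integer RNG seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(N_anc = 200L, N_A = 200L, N_B = 200L, t_split = 150L,
                       L = 500000L, mu = 2.5e-7, rho = 2.5e-7,
                       n_sample_A = 8L, n_sample_B = 6L, burn_in = 300L,
                       seed = 1L) {
  p <- list(N_anc = as.integer(N_anc), N_A = as.integer(N_A),
            N_B = as.integer(N_B), t_split = as.integer(t_split),
            L = as.integer(L), mu = mu, rho = rho,
            n_sample_A = as.integer(n_sample_A),
            n_sample_B = as.integer(n_sample_B),
            burn_in = as.integer(burn_in), seed = as.integer(seed))
  stopifnot(p$N_anc > 0, p$N_A > 0, p$N_B > 0, p$t_split >= 0, p$L > 0,
            mu > 0, rho >= 0, p$n_sample_A > 0, p$n_sample_B > 0,
            p$n_sample_A <= p$N_A, p$n_sample_B <= p$N_B, p$burn_in >= 0)
  class(p) <- "sim_params"
  p
}

#' Sweep parameters for the test population
#'
#' An additive sweep: genotype fitnesses 1, 1+s, 1+2s at one site in
#' population A, acting from generation `t_start` after the split. A
#' standing variant (the default origin) is picked from sites segregating
#' at the split whose frequency is close to `init_freq` and whose position
#' lies in the central part of the chromosome; a new-mutation origin
#' injects a single copy instead. If the allele is lost -- or, when
#' `condition_freq` is set, fails to reach that population frequency by
#' sampling time -- the post-split evolution of A restarts, consuming the
#' same RNG stream, up to `max_retries` times.
#'
#' @param s selection coefficient (> 0).
#' @param origin `"standing"` or `"new"`.
#' @param t_start generations after the split at which selection starts.
#' @param init_freq target initial frequency for a standing variant.
#' @param init_band acceptable frequency band for the standing variant.
#' @param region central fraction of the chromosome eligible for the sweep
#'   site.
#' @param pos fixed sweep position in bp for a new-mutation origin
#'   (`NA` = uniform random in `region`).
#' @param condition_freq population frequency of the swept allele required
#'   at sampling time: a minimum, or a `c(lo, hi)` interval to demand an
#'   ongoing near-fixation sweep (rejecting runs that fixed long before
#'   sampling and have begun to recover diversity); `NA` = only condition
#'   on non-loss.
#' @param max_retries restart cap before erroring.
#' @return A list of class `sweep_params`.
#' @export
sweep_params <- function(s = 0.05, origin = c("standing", "new"),
                         t_start = 0L, init_freq = 0.08,
                         init_band = c(0.03, 0.20), region = c(0.25, 0.75),
                         pos = NA_integer_, condition_freq = NA_real_,
                         max_retries = 100L) {
  origin <- match.arg(origin)
  stopifnot(s > 0, t_start >= 0, init_freq > 0, init_freq < 1,
            length(init_band) == 2L, length(region) == 2L, max_retries >= 1)
  structure(list(s = s, origin = origin, t_start = as.integer(t_start),
                 init_freq = init_freq, init_band = init_band,
                 region = region, pos = pos, condition_freq = condition_freq,
                 max_retries = as.integer(max_retries)),
            class = "sweep_params")
}

# Coalescent-seeded initial population: a Kingman genealogy of n_hap tips
# in a population of N diploids, with infinite-sites mutations dropped on
# branches at rate mu per bp per generation. No recombination here; the
# forward equilibration phase supplies it.
coalescent_init <- function(n_hap, N, mu, L) {
  lineages <- as.list(seq_len(n_hap))
  k <- n_hap
  usedv <- logical(L)
  mut_pos <- integer(0)
  mut_tips <- list()
  while (k > 1L) {
    t_gen <- rexp(1L, rate = k * (k - 1) / 2 / (2 * N))
    nm <- rpois(k, mu * L * t_gen)
    for (i in which(nm > 0L)) {
      for (j in seq_len(nm[i])) {
        repeat {
          p <- sample.int(L, 1L)
          if (!usedv[p]) break
        }
        usedv[p] <- TRUE
        mut_pos[length(mut_pos) + 1L] <- p
        mut_tips[[length(mut_tips) + 1L]] <- lineages[[i]]
      }
    }
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    lineages[[i]] <- c(lineages[[i]], lineages[[j]])
    lineages[[j]] <- lineages[[k]]
    lineages[[k]] <- NULL
    k <- k - 1L
  }
  S <- length(mut_pos)
  alleles <- matrix(0L, nrow = n_hap, ncol = S)
  for (s in seq_len(S)) alleles[mut_tips[[s]], s] <- 1L
  list(alleles = alleles, positions = mut_pos)
}

#' Simulate two diverged populations with an optional selective sweep
#'
#' Discrete-generation Wright-Fisher forward simulation: a
#' coalescent-seeded ancestral population is equilibrated forward under
#' mutation and recombination, split into populations A and B, and evolved
#' independently for `t_split` generations, with optional additive
#' selection at one site in A. Sampling returns phased haplotypes of
#' randomly drawn diploids; fixed differences between A and B are retained
#' as variants, and every emitted variant is polymorphic across the two
#' samples combined. Fully reproducible under `params$seed`.
#'
#' @param params a [sim_params()].
#' @param sweep a [sweep_params()], or `NULL` for neutral evolution.
#' @return A list with `hapA`, `hapB` ([haplotype_matrix()] objects with
#'   populations `"A"` and `"B"`), `variants` (a [variant_table()] with
#'   synthetic quality annotations), `truth` (a `sweep_truth` list, `NULL`
#'   for neutral runs) and `params`.
#' @export
simulate_two_pops <- function(params = sim_params(), sweep = NULL) {
  set.seed(params$seed)
  L <- params$L

  init <- coalescent_init(2L * params$N_anc, params$N_anc, params$mu, L)
  anc <- wf_evolve_cpp(init$alleles, init$positions, params$N_anc,
                       params$burn_in, params$mu, params$rho, L,
                       -1L, 0, integer(0))
  fixed_anc <- anc$fixed
  anc_haps <- anc$haps
  anc_pos <- anc$positions

  # reference population B evolves first (neutral)
  resB <- wf_evolve_cpp(anc_haps, anc_pos, params$N_B, params$t_split,
                        params$mu, params$rho, L, -1L, 0, fixed_anc)
  forbid_A <- c(fixed_anc, resB$positions, resB$fixed)

  truth <- NULL
  if (is.null(sweep)) {
    resA <- wf_evolve_cpp(anc_haps, anc_pos, params$N_A, params$t_split,
                          params$mu, params$rho, L, -1L, 0, forbid_A)
  } else {
    sw <- prepare_sweep(anc_haps, anc_pos, sweep, L, forbid_A)
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > sweep$max_retries)
        stop("sweep failed to establish after ", sweep$max_retries,
             " restarts")
      stateH <- sw$haps; stateP <- sw$positions
      extra_fixed <- integer(0)
      if (sweep$t_start > 0L) {
        r0 <- wf_evolve_cpp(stateH, stateP, params$N_A, sweep$t_start,
                            params$mu, params$rho, L, -1L, 0, forbid_A)
        if (!(sw$pos %in% c(r0$positions, r0$fixed))) next  # lost pre-selection
        stateH <- r0$haps; stateP <- r0$positions
        extra_fixed <- r0$fixed
      }
      resA <- wf_evolve_cpp(stateH, stateP, params$N_A,
                            params$t_split - sweep$t_start,
                            params$mu, params$rho, L, sw$pos, sweep$s,
                            c(forbid_A, extra_fixed))
      resA$fixed <- c(extra_fixed, resA$fixed)
      if (resA$sel_lost) next
      cf <- sweep$condition_freq
      if (!all(is.na(cf))) {
        if (resA$sel_freq < cf[1L]) next
        if (length(cf) > 1L && resA$sel_freq > cf[2L]) next
      }
      break
    }
    truth <- structure(list(sweep_pos = sw$pos, s = sweep$s,
                            t_start = sweep$t_start, origin = sweep$origin,
                            pop_final_freq = resA$sel_freq,
                            final_freq = NA_real_, attempts = attempts),
                       class = "sweep_truth")
  }

  # sample diploids and assemble the shared variant grid
  sampA <- hap_rows(sample.int(params$N_A, params$n_sample_A))
  sampB <- hap_rows(sample.int(params$N_B, params$n_sample_B))
  MA <- resA$haps[sampA, , drop = FALSE]
  MB <- resB$haps[sampB, , drop = FALSE]

  all_pos <- sort(unique(c(resA$positions, resA$fixed,
                           resB$positions, resB$fixed)))
  valA <- grid_values(MA, resA$positions, resA$fixed, all_pos)
  valB <- grid_values(MB, resB$positions, resB$fixed, all_pos)
  tot <- colSums(valA) + colSums(valB)
  keep <- tot > 0L & tot < nrow(valA) + nrow(valB)
  all_pos <- all_pos[keep]
  valA <- valA[, keep, drop = FALSE]
  valB <- valB[, keep, drop = FALSE]

  idsA <- paste0("A", seq_len(params$n_sample_A))
  idsB <- paste0("B", seq_len(params$n_sample_B))
  hapA <- haplotype_matrix(valA, all_pos, chrom = "1", sample_ids = idsA,
                           population = "A")
  hapB <- haplotype_matrix(valB, all_pos, chrom = "1", sample_ids = idsB,
                           population = "B")

  if (!is.null(truth)) {
    j <- match(truth$sweep_pos, all_pos)
    truth$final_freq <- if (is.na(j)) {
      # swept allele fixed in the A sample and absent from the grid only if
      # also fixed in B (impossible post-conditioning) -- treat as fixed
      1.0
    } else mean(valA[, j])
  }

  nv <- length(all_pos)
  ra <- ref_alt_pairs(nv)
  variants <- variant_table(
    chrom = "1", pos = all_pos, ref = ra$ref, alt = ra$alt,
    qual = round(rgamma(nv, shape = 4, scale = 30), 2),
    mq0 = rpois(nv, 0.3),
    qd = round(rgamma(nv, shape = 5, scale = 3), 2),
    fs = round(rexp(nv, rate = 1 / 3), 3))

  list(hapA = hapA, hapB = hapB, variants = variants, truth = truth,
       params = params)
}

hap_rows <- function(diploids) as.vector(rbind(2L * diploids - 1L,
                                               2L * diploids))

# expand a sampled matrix onto the union position grid: fixed positions of
# the population contribute allele 1 everywhere, absent positions allele 0
grid_values <- function(M, active_pos, fixed_pos, all_pos) {
  out <- matrix(0L, nrow = nrow(M), ncol = length(all_pos))
  j <- match(active_pos, all_pos)
  ok <- !is.na(j)
  out[, j[ok]] <- M[, ok, drop = FALSE]
  jf <- match(fixed_pos, all_pos)
  jf <- jf[!is.na(jf)]
  if (length(jf)) out[, jf] <- 1L
  out
}

ref_alt_pairs <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  list(ref = ref, alt = unname(alt))
}

# choose or inject the sweep allele at the split state
prepare_sweep <- function(haps, positions, sweep, L, forbid = integer(0)) {
  if (sweep$origin == "standing") {
    f <- colMeans(haps)
    lo <- as.integer(sweep$region[1L] * L)
    hi <- as.integer(sweep$region[2L] * L)
    cand <- which(f >= sweep$init_band[1L] & f <= sweep$init_band[2L] &
                    positions >= lo & positions <= hi)
    if (!length(cand))
      cand <- which(f > 0 & f < 0.5 & positions >= lo & positions <= hi)
    if (!length(cand)) stop("no standing variant available for the sweep")
    j <- cand[which.min(abs(f[cand] - sweep$init_freq))]
    list(haps = haps, positions = positions, pos = positions[j],
         origin = "standing")
  } else {
    pos <- sweep$pos
    if (is.na(pos)) {
      lo <- as.integer(sweep$region[1L] * L)
      hi <- as.integer(sweep$region[2L] * L)
      repeat {
        pos <- sample(seq(lo, hi), 1L)
        if (!(pos %in% positions) && !(pos %in% forbid)) break
      }
    }
    if (pos %in% positions || pos %in% forbid)
      stop("sweep position collides with a variant")
    carrier <- sample.int(nrow(haps), 1L)
    col <- integer(nrow(haps))
    col[carrier] <- 1L
    list(haps = cbind(haps, col), positions = c(positions, as.integer(pos)),
         pos = as.integer(pos), origin = "new")
  }
}

#' Hudson F_ST between two sampled populations
#'
#' The per-SNP Hudson estimator
#' `((pA - pB)^2 - pA qA/(nA - 1) - pB qB/(nB - 1)) / (pA qB + pB qA)`
#' combined across SNPs as a ratio of sums, the recommended low-bias
#' averaging for sample-based frequencies.
#'
#' @param hapA,hapB [haplotype_matrix()] objects on a shared grid.
#' @return The genome-wide F_ST estimate.
#' @export
fst_hudson <- function(hapA, hapB) {
  check_shared_grid(hapA, hapB)
  pA <- colMeans(hapA$alleles); pB <- colMeans(hapB$alleles)
  nA <- n_haplotypes(hapA); nB <- n_haplotypes(hapB)
  num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}

#' Write a complete synthetic input bundle for a named scenario
#'
#' Presets: `"neutral"` (two diverged populations, no selection),
#' `"sweep"` (an additive s = 0.05 sweep from a standing variant in
#' population A, conditioned on reaching frequency 0.9), and
#' `"ld_contrast"` (population B passes through a strong bottleneck,
#' N_B = 40, so its LD decay curve sits above A's). Each bundle holds a
#' phased VCF, a sample-to-population map, a BED4 file of genes tiling the
#' chromosome, and the ground truth as a flat key=value record, and loads
#' cleanly through [read_vcf()].
#'
#' @param name one of `"neutral"`, `"sweep"`, `"ld_contrast"`.
#' @param seed integer RNG seed.
#' @param out_dir directory to write into (created if needed).
#' @return A list with the simulation objects (`hapA`, `hapB`, `variants`,
#'   `truth`, `params`) and file paths (`vcf`, `popmap`, `genes`,
#'   `truth_file`).
#' @export
scenario <- function(name = c("neutral", "sweep", "ld_contrast"), seed = 1L,
                     out_dir = tempfile("sweepscan_")) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1L],
         "'; available: neutral, sweep, ld_contrast"))
  params <- switch(name,
    neutral = sim_params(seed = seed),
    sweep = sim_params(seed = seed),
    ld_contrast = sim_params(N_B = 40L, seed = seed))
  sweep <- if (name == "sweep")
    sweep_params(s = 0.05, origin = "new", condition_freq = 0.9) else NULL

  sim <- simulate_two_pops(params, sweep)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  vcf_path <- file.path(out_dir, "sim.vcf")
  write_vcf(sim$variants, list(A = sim$hapA, B = sim$hapB), vcf_path,
            chrom_length = params$L)

  popmap_path <- file.path(out_dir, "popmap.txt")
  ids <- function(h) h$sample_ids[seq(1L, length(h$sample_ids), by = 2L)]
  write.table(data.frame(sample = c(ids(sim$hapA), ids(sim$hapB)),
                         population = rep(c("A", "B"),
                                          c(params$n_sample_A,
                                            params$n_sample_B))),
              popmap_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  genes_path <- file.path(out_dir, "genes.bed")
  gstart <- seq(0L, params$L - 20000L, by = 20000L)
  write.table(data.frame(chrom = "1", start = gstart, end = gstart + 12000L,
                         name = sprintf("gene%02d", seq_along(gstart))),
              genes_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  truth_path <- file.path(out_dir, "truth.txt")
  tr <- sim$truth
  kv <- c(scenario = name, seed = seed, L = params$L,
          t_split = params$t_split, N_A = params$N_A, N_B = params$N_B,
          if (!is.null(tr)) c(sweep_pos = tr$sweep_pos, s = tr$s,
                              t_start = tr$t_start, origin = tr$origin,
                              final_freq = tr$final_freq,
                              pop_final_freq = tr$pop_final_freq))
  writeLines(paste0(names(kv), "=", unlist(kv)), truth_path)

  c(sim, list(vcf = vcf_path, popmap = popmap_path, genes = genes_path,
              truth_file = truth_path, dir = out_dir))
}
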