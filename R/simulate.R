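#' Isolation-with-migration scenario
#'
#' Parameters of a two-population coalescent scenario used to generate
#' "general" training data: `theta` is the per-site scaled mutation rate
#' (4N mu), `mig` the scaled migration rate 4Nm (symmetric), and `tau` the
#' divergence time in units of 2N generations. `label` marks the cell as
#' same-species (-1), different-species (+1), or `NA` (unlabeled,
#' excluded from training).
#'
#' @param theta per-site scaled mutation rate (> 0).
#' @param mig scaled migration rate 4Nm (>= 0).
#' @param tau divergence time in 2N generations (>= 0).
#' @param n_loci,locus_length,haplotypes_per_pop dataset dimensions.
#' @param label -1, 1 or NA.
#' @return an object of class `im_scenario`.
#' @export
im_scenario <- function(theta, mig, tau, n_loci = 50L, locus_length = 500L,
                        haplotypes_per_pop = 2L, label = NA_integer_) {
  stopifnot(theta > 0, mig >= 0, tau >= 0, n_loci >= 1L, locus_length >= 1L,
            haplotypes_per_pop >= 1L, is.na(label) || label %in% c(-1L, 1L))
  structure(list(theta = theta, mig = mig, tau = tau,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 haplotypes_per_pop = as.integer(haplotypes_per_pop),
                 label = as.integer(label)),
            class = "im_scenario")
}

#' Hierarchical reference-genus configuration
#'
#' Describes a simulated genus with `n_species` species, each containing
#' `pops_per_species` populations that diverged at the shallow depth
#' `tau_pop` (with symmetric within-species migration), while species split
#' at depths that are multiples of `tau_species` (balanced pairing rounds,
#' so species divergences span recent and older depths). Times are in 2N
#' generations. With probability `co_location_rate` a population shares its
#' locality with the previous population of its own species, so co-located
#' units are always conspecific.
#'
#' @param n_species number of species (>= 2).
#' @param pops_per_species populations per species (>= 1).
#' @param tau_species,tau_pop split depths, `tau_species > tau_pop >= 0`.
#' @param within_species_mig scaled migration 4Nm among conspecific
#'   populations.
#' @param theta per-site scaled mutation rate.
#' @param n_loci,locus_length,haplotypes_per_pop dataset dimensions.
#' @param co_location_rate probability in `[0, 1]`.
#' @return an object of class `genus_config`.
#' @export
genus_config <- function(n_species = 3L, pops_per_species = 2L,
                         tau_species = 3, tau_pop = 0.2,
                         within_species_mig = 1, theta = 0.005,
                         n_loci = 50L, locus_length = 500L,
                         haplotypes_per_pop = 2L, co_location_rate = 0.5) {
  stopifnot(n_species >= 2L, pops_per_species >= 1L,
            tau_species > tau_pop, tau_pop >= 0, within_species_mig >= 0,
            theta > 0, co_location_rate >= 0, co_location_rate <= 1)
  structure(list(n_species = as.integer(n_species),
                 pops_per_species = as.integer(pops_per_species),
                 tau_species = tau_species, tau_pop = tau_pop,
                 within_species_mig = within_species_mig, theta = theta,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 haplotypes_per_pop = as.integer(haplotypes_per_pop),
                 co_location_rate = co_location_rate),
            class = "genus_config")
}

# Fixed seed-splitting rule: derive a child stream seed from (seed, i).
# All arithmetic in doubles, result an integer in [1, 2147483586].
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483587 * 48271 +
                as.numeric(i) * 16807) %% 2147483587) + 1L
}

# Structured-coalescent genealogy with a deme-merge schedule.
# n_per_deme: named integer vector (names become tip-label prefixes);
# mig: K x K matrix of scaled rates 4Nm (row = source deme);
# merges: data.frame(time, from, to) sorted by time, deme indices.
# Time unit: 2N generations (pair coalescence rate 1 within a deme;
# per-lineage migration rate 4Nm/2). Returns a newick string.
sim_genealogy <- function(n_per_deme, mig, merges) {
  K <- length(n_per_deme)
  deme <- rep(seq_len(K), n_per_deme)
  nwk <- unlist(lapply(seq_len(K), function(d)
    paste0(names(n_per_deme)[d], "_h", seq_len(n_per_deme[d]))))
  height <- numeric(length(nwk))
  t <- 0
  mi <- 1L
  merges <- merges[order(merges$time), , drop = FALSE]
  repeat {
    if (length(nwk) == 1L) break
    kd <- tabulate(deme, nbins = K)
    coal <- kd * (kd - 1) / 2
    migr <- (mig / 2)[deme, , drop = FALSE]
    rate <- sum(coal) + sum(migr)
    dt <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (mi <= nrow(merges) && t + dt >= merges$time[mi]) {
      t <- merges$time[mi]
      deme[deme == merges$from[mi]] <- merges$to[mi]
      mig[merges$from[mi], ] <- 0
      mig[, merges$from[mi]] <- 0
      mi <- mi + 1L
      next
    }
    if (!is.finite(dt))
      stop("genealogy cannot coalesce: isolated lineages with no merge event")
    t <- t + dt
    if (stats::runif(1L) < sum(coal) / rate) {
      d <- sample.int(K, 1L, prob = coal)
      pair <- sample(which(deme == d), 2L)
      new_nwk <- sprintf("(%s:%.12g,%s:%.12g)",
                         nwk[pair[1L]], t - height[pair[1L]],
                         nwk[pair[2L]], t - height[pair[2L]])
      keep <- -pair
      nwk <- c(nwk[keep], new_nwk)
      height <- c(height[keep], t)
      deme <- c(deme[keep], d)
    } else {
      # migration: pick (lineage, destination) proportional to rates
      idx <- sample.int(length(migr), 1L, prob = as.vector(migr))
      lin <- (idx - 1L) %% nrow(migr) + 1L
      dst <- (idx - 1L) %/% nrow(migr) + 1L
      deme[lin] <- dst
    }
  }
  paste0(nwk, ";")
}

# Simulate one locus: genealogy + finite-sites Jukes-Cantor mutations.
# Branch lengths are in 2N generations, so the per-site substitution rate is
# theta/2 (theta = 4N mu). Returns an upper-case character matrix.
sim_locus <- function(n_per_deme, mig, merges, theta, locus_length, lseed) {
  set.seed(lseed)
  nwk <- sim_genealogy(n_per_deme, mig, merges)
  tree <- ape::read.tree(text = nwk)
  sq <- phangorn::simSeq(tree, l = locus_length, rate = theta / 2)
  m <- toupper(as.character(sq))
  rownames(m) <- names(sq)
  m
}

#' Simulate a two-population isolation-with-migration dataset
#'
#' Coalescent simulation of two demes that split `tau` (2N generations) ago
#' with symmetric scaled migration `4Nm = mig` since the split; independent
#' loci; finite-sites Jukes-Cantor mutations at per-site rate `theta`.
#' Deterministic given `seed` (per-locus seeds derived by a fixed splitting
#' rule).
#'
#' @param sc an [im_scenario].
#' @param seed integer master seed.
#' @return a [multilocus_dataset] with populations `pop1`, `pop2`.
#' @export
simulate_im_pair <- function(sc, seed) {
  stopifnot(inherits(sc, "im_scenario"))
  n <- stats::setNames(rep(sc$haplotypes_per_pop, 2L), c("pop1", "pop2"))
  mig <- matrix(c(0, sc$mig, sc$mig, 0), 2L, 2L)
  merges <- data.frame(time = sc$tau, from = 2L, to = 1L)
  loci <- lapply(seq_len(sc$n_loci), function(i)
    sim_locus(n, mig, merges, sc$theta, sc$locus_length, derive_seed(seed, i)))
  names(loci) <- sprintf("locus%03d", seq_len(sc$n_loci))
  sm <- data.frame(
    sample = unlist(lapply(names(n), function(p)
      paste0(p, "_h", seq_len(sc$haplotypes_per_pop)))),
    population = rep(names(n), each = sc$haplotypes_per_pop),
    locality = rep(c("loc1", "loc2"), each = sc$haplotypes_per_pop))
  multilocus_dataset(loci, sm)
}

#' Simulate a hierarchical multi-species reference genus
#'
#' Generates a labeled dataset emulating a reference taxon with robustly
#' known species limits: species that split at deep, staggered times, each
#' containing populations that diverged recently and still exchange
#' migrants. The output carries species and locality labels and, by
#' construction, passes [filter_complete_matrix()] unchanged.
#'
#' @param gc a [genus_config].
#' @param seed integer master seed.
#' @return a [multilocus_dataset] with a species column; populations are
#'   named `s<i>p<j>`, species `sp<i>`.
#' @export
simulate_reference_genus <- function(gc, seed) {
  stopifnot(inherits(gc, "genus_config"))
  S <- gc$n_species; P <- gc$pops_per_species
  K <- S * P
  pop_names <- as.vector(t(outer(seq_len(S), seq_len(P),
                                 function(s, p) sprintf("s%dp%d", s, p))))
  species_of_deme <- rep(seq_len(S), each = P)
  n <- stats::setNames(rep(gc$haplotypes_per_pop, K), pop_names)
  mig <- matrix(0, K, K)
  for (s in seq_len(S)) {
    idx <- which(species_of_deme == s)
    mig[idx, idx] <- gc$within_species_mig
  }
  diag(mig) <- 0
  # within-species merges at tau_pop (star into each species' first deme)
  merges <- do.call(rbind, lapply(seq_len(S), function(s) {
    idx <- which(species_of_deme == s)
    if (length(idx) < 2L) return(NULL)
    data.frame(time = gc$tau_pop, from = idx[-1L], to = idx[1L])
  }))
  # balanced pairing rounds among species at r * tau_species
  reps <- which(!duplicated(species_of_deme))   # first deme of each species
  r <- 1L
  while (length(reps) > 1L) {
    nxt <- reps[c(TRUE, FALSE)]
    for (i in seq_len(length(reps) %/% 2L)) {
      merges <- rbind(merges, data.frame(time = r * gc$tau_species,
                                         from = reps[2L * i],
                                         to = reps[2L * i - 1L]))
    }
    reps <- nxt[seq_len(ceiling(length(reps) / 2))]
    r <- r + 1L
  }
  # locality map drawn from the map-level stream (derived index 0)
  set.seed(derive_seed(seed, 0L))
  locality <- stats::setNames(sprintf("loc%02d", seq_len(K)), pop_names)
  for (s in seq_len(S)) {
    idx <- which(species_of_deme == s)
    for (j in idx[-1L]) {
      if (stats::runif(1L) < gc$co_location_rate)
        locality[j] <- locality[j - 1L]   # demes of a species are consecutive
    }
  }
  loci <- lapply(seq_len(gc$n_loci), function(i)
    sim_locus(n, mig, merges, gc$theta, gc$locus_length, derive_seed(seed, i)))
  names(loci) <- sprintf("locus%03d", seq_len(gc$n_loci))
  sm <- data.frame(
    sample = unlist(lapply(pop_names, function(p)
      paste0(p, "_h", seq_len(gc$haplotypes_per_pop)))),
    population = rep(pop_names, each = gc$haplotypes_per_pop),
    locality = rep(unname(locality), each = gc$haplotypes_per_pop),
    species = rep(sprintf("sp%d", species_of_deme), each = gc$haplotypes_per_pop))
  multilocus_dataset(loci, sm)
}

#' The default "general" training grid
#'
#' The cross of theta in \{0.001, 0.005, 0.01\}, 4Nm in \{0, 0.1, 1, 10\}
#' and tau in \{0, 0.5, 1, 2, 5\} (2N generations). Cells are auto-labeled
#' same-species (-1) when `tau = 0` or `4Nm >= 10`, different-species (+1)
#' when `tau >= 1` and `4Nm <= 0.1`; ambiguous intermediate cells are left
#' unlabeled and excluded from training by default.
#'
#' @param n_loci,locus_length,haplotypes_per_pop dimensions applied to every
#'   cell.
#' @return list of [im_scenario] objects.
#' @export
default_general_grid <- function(n_loci = 50L, locus_length = 500L,
                                 haplotypes_per_pop = 2L) {
  cells <- expand.grid(theta = c(0.001, 0.005, 0.01),
                       mig = c(0, 0.1, 1, 10),
                       tau = c(0, 0.5, 1, 2, 5))
  lapply(seq_len(nrow(cells)), function(i) {
    th <- cells$theta[i]; mg <- cells$mig[i]; ta <- cells$tau[i]
    lab <- if (ta == 0 || mg >= 10) -1L
           else if (ta >= 1 && mg <= 0.1) 1L
           else NA_integer_
    im_scenario(th, mg, ta, n_loci, locus_length, haplotypes_per_pop, lab)
  })
}
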