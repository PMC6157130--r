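#' Simulate nuclear-family pedigrees
#'
#' Generates a set of nuclear families (two unrelated founders plus a random
#' number of full-sib offspring) emulating the family structure of a
#' lipid-lowering family study in which roughly 810 genotyped individuals come
#' from 172 families. Only nuclear families are produced; extended pedigrees
#' are out of scope because nuclear structure already induces the within-family
#' correlation that the clustered sandwich estimator must absorb.
#'
#' @param n_families number of families (>= 1).
#' @param size_probs named numeric vector of family-size probabilities; names
#'   are total family sizes (founders included, so sizes are >= 2). The default
#'   averages ~4.7 members so that 172 families yield ~810 individuals.
#' @param n_total optional total individual count. When supplied, offspring are
#'   added to / removed from randomly chosen families (never below size 2)
#'   until the pedigree holds exactly `n_total` individuals.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return a `data.frame` with columns `individual_id`, `family_id`,
#'   `father_id`, `mother_id` (NA for founders) and `sex` (0 = male,
#'   1 = female). Founder couples are one male and one female; offspring sex is
#'   Bernoulli(1/2).
#' @examples
#' ped <- simulate_pedigrees(5, seed = 1)
#' table(ped$family_id)
#' @export
simulate_pedigrees <- function(n_families,
                               size_probs = default_family_size_probs(),
                               n_total = NULL,
                               seed = NULL) {
  if (!is.numeric(n_families) || length(n_families) != 1L || n_families < 1)
    stop_bad_arg("n_families must be a positive count")
  n_families <- as.integer(n_families)
  sizes_avail <- as.integer(names(size_probs))
  if (anyNA(sizes_avail) || any(sizes_avail < 1))
    stop_bad_arg("size_probs must be named by integer family sizes >= 1")
  check_prob(size_probs, "size_probs")
  if (!is.null(seed)) set.seed(seed)

  sizes <- if (length(sizes_avail) == 1L) rep(sizes_avail, n_families) else
    sample(sizes_avail, n_families, replace = TRUE,
           prob = size_probs / sum(size_probs))
  if (!is.null(n_total)) {
    if (n_total < 2L * n_families)
      stop_bad_arg("n_total too small for ", n_families, " nuclear families")
    while (sum(sizes) > n_total) {
      i <- sample(which(sizes > 2L), 1L)
      sizes[i] <- sizes[i] - 1L
    }
    while (sum(sizes) < n_total) {
      i <- sample.int(n_families, 1L)
      sizes[i] <- sizes[i] + 1L
    }
  }

  fam_id <- sprintf("F%04d", seq_len(n_families))
  rows <- vector("list", n_families)
  counter <- 0L
  for (f in seq_len(n_families)) {
    sz <- sizes[f]
    ids <- sprintf("I%05d", counter + seq_len(sz))
    counter <- counter + sz
    n_off <- max(sz - 2L, 0L)
    if (sz == 1L) {
      # degenerate single-founder family (only reachable via size_probs)
      rows[[f]] <- data.frame(individual_id = ids, family_id = fam_id[f],
                              father_id = NA_character_,
                              mother_id = NA_character_,
                              sex = rbinom(1L, 1L, 0.5),
                              stringsAsFactors = FALSE)
      next
    }
    sex <- c(0L, 1L, if (n_off > 0L) rbinom(n_off, 1L, 0.5))
    rows[[f]] <- data.frame(
      individual_id = ids,
      family_id = fam_id[f],
      father_id = c(NA_character_, NA_character_, rep(ids[1L], n_off)),
      mother_id = c(NA_character_, NA_character_, rep(ids[2L], n_off)),
      sex = sex,
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Default family-size distribution
#'
#' Family sizes 2-8 with mean ~4.71, so that 172 families average ~810
#' members. The source study does not print its family-size distribution; this
#' default is a documented guess.
#' @return named probability vector.
#' @export
default_family_size_probs <- function() {
  c(`2` = 0.08, `3` = 0.17, `4` = 0.22, `5` = 0.22,
    `6` = 0.16, `7` = 0.10, `8` = 0.05)
}

#' Simulate SNP dosages on a pedigree
#'
#' Founders receive two independent alleles at the effect-allele frequency
#' (Hardy-Weinberg); each offspring receives one uniformly chosen allele from
#' each parent (Mendelian transmission). Marginally every individual's dosage
#' is Binomial(2, eaf), but dosages are correlated within families.
#'
#' @param pedigree a table from [simulate_pedigrees()].
#' @param eaf effect-allele frequency in `[0, 1]`.
#' @param seed integer seed.
#' @return integer vector of dosages in `{0, 1, 2}`, aligned with
#'   `pedigree$individual_id`.
#' @examples
#' ped <- simulate_pedigrees(10, seed = 1)
#' g <- simulate_genotypes(ped, eaf = 0.636, seed = 2)
#' mean(g)  # ~ 2 * 0.636
#' @export
simulate_genotypes <- function(pedigree, eaf, seed = NULL) {
  check_prob(eaf, "eaf")
  if (length(eaf) != 1L) stop_bad_arg("eaf must be a single frequency")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pedigree)
  founder <- is.na(pedigree$father_id) & is.na(pedigree$mother_id)
  a1 <- integer(n); a2 <- integer(n)
  a1[founder] <- rbinom(sum(founder), 1L, eaf)
  a2[founder] <- rbinom(sum(founder), 1L, eaf)
  idx <- match(pedigree$individual_id, pedigree$individual_id)
  off <- which(!founder)
  if (length(off)) {
    fa <- match(pedigree$father_id[off], pedigree$individual_id)
    mo <- match(pedigree$mother_id[off], pedigree$individual_id)
    if (anyNA(fa) || anyNA(mo))
      stop_bad_arg("offspring reference parents absent from the pedigree")
    pick_f <- runif(length(off)) < 0.5
    pick_m <- runif(length(off)) < 0.5
    a1[off] <- ifelse(pick_f, a1[fa], a2[fa])
    a2[off] <- ifelse(pick_m, a1[mo], a2[mo])
  }
  as.integer(a1 + a2)
}
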