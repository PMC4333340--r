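# Forward simulation of experimental crosses segregating one biallelic
# autosomal causal locus. Meiosis is modelled at marker resolution: a gamete
# is an ancestry state (carrier/non-carrier) at each locus of the chromosome
# grid, with a Haldane (no-interference) recombination Bernoulli draw in
# each inter-locus interval. The causal position is carried as a
# pseudo-marker on its chromosome so that phenotype draws condition on the
# exact causal genotype.

#' Penetrance and anomaly-class model
#'
#' Phenotype model for a single incompletely dominant, incompletely
#' penetrant causal locus. Defaults describe the rat renal-agenesis
#' phenotype: 13.4% penetrance in homozygous carriers (the ACI strain
#' incidence), half that in heterozygotes, none in non-carriers; affected
#' animals split 67.8/18.8/13.4% across URA/URH/HUN; URA is right-sided
#' with probability 0.84. Set `q_right = 0.5` to emulate a background with
#' no laterality bias (the congenic strains); URH and HUN sides are always
#' uniform, and bilateral presentation (HUN only) has probability
#' `p_bilateral_hun`, default 0 (2 of 4994 observed).
#'
#' @param p_CC,p_CH,p_NN penetrance by causal genotype, each in [0,1] with
#'   `p_NN <= p_CH <= p_CC` (incomplete dominance).
#' @param class_mix probabilities over URA, URH, HUN given affected;
#'   must sum to 1.
#' @param q_right probability a URA is right-sided.
#' @param p_bilateral_hun probability a HUN presents bilaterally.
#' @return a `penetrance_model` list.
#' @export
penetrance_model <- function(p_CC = 0.134, p_CH = 0.067, p_NN = 0,
                             class_mix = c(URA = 0.678, URH = 0.188,
                                           HUN = 0.134),
                             q_right = 0.84, p_bilateral_hun = 0) {
  probs <- c(p_CC, p_CH, p_NN, class_mix, q_right, p_bilateral_hun)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0,1]")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (!(p_NN <= p_CH && p_CH <= p_CC))
    stop("incomplete dominance requires p_NN <= p_CH <= p_CC")
  if (is.null(names(class_mix))) names(class_mix) <- ANOMALY_CLASSES
  stopifnot(identical(sort(names(class_mix)), sort(ANOMALY_CLASSES)))
  structure(list(p_CC = p_CC, p_CH = p_CH, p_NN = p_NN,
                 class_mix = class_mix[ANOMALY_CLASSES],
                 q_right = q_right, p_bilateral_hun = p_bilateral_hun),
            class = "penetrance_model")
}

# ancestry gametes from one parent on one chromosome's locus grid.
# h1, h2: 0/1 ancestry vectors (1 = carrier/donor); pos_cm sorted loci.
# Returns n x L integer matrix.
sim_gametes <- function(h1, h2, pos_cm, n = 1L) {
  L <- length(pos_cm)
  stopifnot(length(h1) == L, length(h2) == L)
  cur <- sample.int(2L, n, replace = TRUE)
  out <- matrix(0L, n, L)
  out[, 1L] <- ifelse(cur == 1L, h1[1L], h2[1L])
  if (L > 1L) {
    r <- haldane_recomb_fraction(diff(pos_cm))
    for (j in 2:L) {
      swap <- stats::runif(n) < r[j - 1L]
      cur <- ifelse(swap, 3L - cur, cur)
      out[, j] <- ifelse(cur == 1L, h1[j], h2[j])
    }
  }
  out
}

#' Simulate gametes from a parent on one chromosome
#'
#' Draws `n` gametes from a parent with the given pair of ancestry
#' haplotypes over the chromosome's markers, recombining between adjacent
#' markers with the Haldane fraction of their cM distance. Crossovers are
#' realized at marker resolution: the returned gamete is the ancestry state
#' at each marker, and a crossover between discordant adjacent markers is
#' located somewhere in that interval.
#'
#' @param parent list with elements `h1` and `h2`, 0/1 vectors
#'   (1 = carrier ancestry) over the chromosome's markers in map order.
#' @param map a [genetic_map()].
#' @param chrom chromosome to simulate.
#' @param n number of gametes.
#' @return `n` x markers integer matrix of carrier ancestries.
#' @export
simulate_gametes <- function(parent, map, chrom, n = 1L) {
  sub <- map_chrom(map, chrom)
  g <- sim_gametes(parent$h1, parent$h2, sub$pos_cm, n)
  colnames(g) <- sub$marker
  g
}

#' An F1 parent (heterozygous carrier at every locus)
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome.
#' @return list(h1, h2) with all-carrier and all-non-carrier haplotypes.
#' @export
f1_parent <- function(map, chrom) {
  L <- nrow(map_chrom(map, chrom))
  list(h1 = rep(1L, L), h2 = rep(0L, L))
}

# locus grid of a chromosome with the causal position inserted as a
# pseudo-marker; genetic position interpolated between flanking markers.
augment_loci <- function(map, chrom, causal_pos_mb) {
  sub <- map_chrom(map, chrom)
  if (causal_pos_mb < min(sub$pos_mb) || causal_pos_mb > max(sub$pos_mb))
    stop("causal position ", causal_pos_mb,
         " Mb outside the marker span of chromosome ", chrom)
  if (causal_pos_mb %in% sub$pos_mb) {
    idx <- match(causal_pos_mb, sub$pos_mb)
    return(list(pos_cm = sub$pos_cm, marker = sub$marker,
                pos_mb = sub$pos_mb, causal_idx = idx,
                marker_idx = seq_len(nrow(sub))))
  }
  causal_cm <- stats::approx(sub$pos_mb, sub$pos_cm,
                             xout = causal_pos_mb)$y
  pos_mb <- c(sub$pos_mb, causal_pos_mb)
  ord <- order(pos_mb)
  list(pos_cm = c(sub$pos_cm, causal_cm)[ord],
       pos_mb = pos_mb[ord],
       marker = c(sub$marker, NA_character_)[ord],
       causal_idx = which(is.na(c(sub$marker, NA_character_)[ord])),
       marker_idx = which(!is.na(c(sub$marker, NA_character_)[ord])))
}

geno_code <- function(g) c("N", "H", "C")[g + 1L]

draw_phenotypes <- function(ids, g_causal, model) {
  n <- length(ids)
  p <- c(model$p_NN, model$p_CH, model$p_CC)[g_causal + 1L]
  affected <- stats::runif(n) < p
  anomaly <- rep("NONE", n)
  side <- rep(NA_character_, n)
  n_aff <- sum(affected)
  if (n_aff > 0L) {
    cls <- sample(ANOMALY_CLASSES, n_aff, replace = TRUE,
                  prob = model$class_mix)
    anomaly[affected] <- cls
    u <- stats::runif(n_aff)
    s <- character(n_aff)
    s[cls == "URA"] <- ifelse(u[cls == "URA"] < model$q_right,
                              "RIGHT", "LEFT")
    s[cls == "URH"] <- ifelse(u[cls == "URH"] < 0.5, "RIGHT", "LEFT")
    hun <- cls == "HUN"
    s[hun] <- ifelse(u[hun] < model$p_bilateral_hun, "BILATERAL",
                     ifelse(stats::runif(sum(hun)) < 0.5, "RIGHT", "LEFT"))
    side[affected] <- s
  }
  phenotype_table(ids, anomaly, side)
}

#' Simulate an F2 intercross
#'
#' Generates `n_progeny` F2 animals from an F1 x F1 intercross: each animal
#' receives two independent F1 gametes per chromosome, genotypes are read
#' off at the map's markers, and the phenotype is drawn from the penetrance
#' model conditional on the genotype at the causal position.
#'
#' @param n_progeny number of F2 animals (> 0).
#' @param map a [genetic_map()].
#' @param model a [penetrance_model()].
#' @param causal_chrom chromosome carrying the causal locus.
#' @param causal_pos_mb causal physical position, within the chromosome's
#'   marker span.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param id_prefix prefix for animal ids.
#' @return an `f2_sim` list: `genotypes` ([genotype_matrix()]),
#'   `phenotypes` ([phenotype_table()]), `causal_genotype` (0/1/2 carrier
#'   dose per animal), and `truth` (per-haplotype ancestry matrices and the
#'   augmented locus grid of the causal chromosome, for validation and
#'   progeny testing).
#' @examples
#' map <- renag1_marker_map()
#' sim <- simulate_f2(200, map, causal_pos_mb = 34.96, seed = 1)
#' table(sim$phenotypes$anomaly)
#' @export
simulate_f2 <- function(n_progeny, map, model = penetrance_model(),
                        causal_chrom = map$chrom[1L], causal_pos_mb,
                        seed = NULL, id_prefix = "F2") {
  if (!is.numeric(n_progeny) || n_progeny <= 0)
    stop("n_progeny must be a positive integer")
  n <- as.integer(n_progeny)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("%s-%04d", id_prefix, seq_len(n))
  calls <- matrix(NA_character_, n, nrow(map),
                  dimnames = list(ids, map$marker))
  truth <- NULL
  g_causal <- NULL
  for (ch in unique(map$chrom)) {
    if (ch == causal_chrom) {
      loci <- augment_loci(map, ch, causal_pos_mb)
      h1 <- sim_gametes(rep(1L, length(loci$pos_cm)),
                        rep(0L, length(loci$pos_cm)), loci$pos_cm, n)
      h2 <- sim_gametes(rep(1L, length(loci$pos_cm)),
                        rep(0L, length(loci$pos_cm)), loci$pos_cm, n)
      g_causal <- h1[, loci$causal_idx] + h2[, loci$causal_idx]
      calls[, loci$marker[loci$marker_idx]] <-
        geno_code(h1[, loci$marker_idx, drop = FALSE] +
                  h2[, loci$marker_idx, drop = FALSE])
      truth <- list(chrom = ch, loci = loci, hap1 = h1, hap2 = h2)
    } else {
      sub <- map_chrom(map, ch)
      L <- length(sub$pos_cm)
      h1 <- sim_gametes(rep(1L, L), rep(0L, L), sub$pos_cm, n)
      h2 <- sim_gametes(rep(1L, L), rep(0L, L), sub$pos_cm, n)
      calls[, sub$marker] <- geno_code(h1 + h2)
    }
  }
  if (is.null(g_causal)) stop("causal_chrom ", causal_chrom, " not in map")
  phen <- draw_phenotypes(ids, g_causal, model)
  structure(list(genotypes = genotype_matrix(calls),
                 phenotypes = phen,
                 causal_genotype = stats::setNames(g_causal, ids),
                 truth = truth, model = model, map = map,
                 causal_chrom = causal_chrom,
                 causal_pos_mb = causal_pos_mb, seed = seed),
            class = "f2_sim")
}

#' Simulate a backcross of one carrier to the recipient strain
#'
#' Progeny of `sire` (two ancestry haplotypes over the augmented locus grid
#' of one chromosome) mated to recipient-strain dams. Each progeny inherits
#' one sire gamete and one all-non-carrier dam haplotype, so marker calls
#' are `H` or `N`; phenotypes are drawn from the causal-locus genotype
#' (heterozygous carrier or non-carrier).
#'
#' @param sire list(h1, h2) of 0/1 ancestry vectors over `loci$pos_cm`.
#' @param loci augmented locus grid, as in the `truth` element of
#'   [simulate_f2()] (fields `pos_cm`, `pos_mb`, `marker`, `causal_idx`,
#'   `marker_idx`).
#' @param model a [penetrance_model()].
#' @param n number of progeny.
#' @param id_prefix prefix for progeny ids.
#' @return list with `genotypes`, `phenotypes`, `gametes` (true sire-gamete
#'   ancestry over the full locus grid) and `causal_genotype` (0/1).
#' @export
simulate_backcross <- function(sire, loci, model = penetrance_model(),
                               n = 30L, id_prefix = "BC") {
  gam <- sim_gametes(sire$h1, sire$h2, loci$pos_cm, n)
  ids <- sprintf("%s-%03d", id_prefix, seq_len(n))
  calls <- matrix(c("N", "H")[gam[, loci$marker_idx, drop = FALSE] + 1L],
                  nrow = n,
                  dimnames = list(ids, loci$marker[loci$marker_idx]))
  g_causal <- gam[, loci$causal_idx]
  phen <- draw_phenotypes(ids, g_causal, model)
  list(genotypes = genotype_matrix(calls), phenotypes = phen,
       gametes = gam, causal_genotype = stats::setNames(g_causal, ids))
}
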