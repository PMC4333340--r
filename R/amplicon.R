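# Diagnostic PCR logic for structural insertion alleles at the rat Hooded
# locus (Kit intron 1): Self = empty site, Irish = solitary 584 bp LTR,
# Hooded = full 7098 bp ERV. A site-flanking primer pair amplifies the
# empty-site product plus whatever is inserted, up to a practical size
# ceiling; a pair anchored inside the element amplifies only from alleles
# that contain the internal primer site.

#' Insertion allele at a structural insertion site
#'
#' The three canonical alleles: `SELF_EMPTY` (no insertion, 0 bp),
#' `IRISH_SOLITARY_LTR` (584 bp solitary LTR) and `HOODED_FULL_ERV`
#' (7098 bp full element with both LTRs; the only allele containing the
#' element-internal primer site). The insertion site (position 34,957,384,
#' Kit intron 1, antisense orientation) is carried as metadata and plays no
#' role in the length arithmetic.
#'
#' @param name one of `"SELF_EMPTY"`, `"IRISH_SOLITARY_LTR"`,
#'   `"HOODED_FULL_ERV"`.
#' @return an `insertion_allele` list: `name`, `insert_length_bp`,
#'   `contains_internal_primer_site`, `insertion_site`, `orientation`.
#' @export
insertion_allele <- function(name = c("SELF_EMPTY", "IRISH_SOLITARY_LTR",
                                      "HOODED_FULL_ERV")) {
  name <- match.arg(name)
  len <- c(SELF_EMPTY = 0L, IRISH_SOLITARY_LTR = 584L,
           HOODED_FULL_ERV = 7098L)[[name]]
  structure(list(name = name, insert_length_bp = len,
                 contains_internal_primer_site = name == "HOODED_FULL_ERV",
                 insertion_site = 34957384, orientation = "antisense"),
            class = "insertion_allele")
}

#' The three Hooded-locus alleles
#'
#' @return named list of [insertion_allele()] objects
#'   (`SELF_EMPTY`, `IRISH_SOLITARY_LTR`, `HOODED_FULL_ERV`).
#' @export
hooded_alleles <- function() {
  names <- c("SELF_EMPTY", "IRISH_SOLITARY_LTR", "HOODED_FULL_ERV")
  stats::setNames(lapply(names, insertion_allele), names)
}

#' Primer pair specification
#'
#' Exactly one parameterization is active: a site-flanking pair has an
#' `empty_site_product_bp` (product grows by the insert length); an
#' element-internal pair has an `internal_product_bp` and amplifies only
#' from alleles containing the internal primer site. The internal product
#' length is a parameter, not computed from flanking arithmetic: the
#' internal primer's offset within the element is generally not published.
#'
#' @param name pair label (e.g. `"AB"`).
#' @param empty_site_product_bp product from the empty site, or `NULL`.
#' @param internal_product_bp product when the internal site is present,
#'   or `NULL`.
#' @param max_amplifiable_bp practical ceiling for standard PCR
#'   (default 5000 bp); longer predicted products yield no band.
#' @return a `primer_pair` list.
#' @export
primer_pair <- function(name, empty_site_product_bp = NULL,
                        internal_product_bp = NULL,
                        max_amplifiable_bp = 5000L) {
  if (is.null(empty_site_product_bp) == is.null(internal_product_bp))
    stop("primer pair ", name,
         ": exactly one of empty_site_product_bp or internal_product_bp",
         " must be given")
  structure(list(name = name,
                 empty_site_product_bp = empty_site_product_bp,
                 requires_internal_site = !is.null(internal_product_bp),
                 internal_product_bp = internal_product_bp,
                 max_amplifiable_bp = max_amplifiable_bp),
            class = "primer_pair")
}

#' The standard Hooded-locus diagnostic primer pairs
#'
#' `AB` flanks the insertion site (1006 bp from the empty site); `CD` is
#' anchored on the element interior (997 bp, full-ERV alleles only).
#'
#' @return named list of [primer_pair()] objects.
#' @export
kit_primer_pairs <- function() {
  list(AB = primer_pair("AB", empty_site_product_bp = 1006L),
       CD = primer_pair("CD", internal_product_bp = 997L))
}

#' Predict the PCR product of a primer pair on an insertion allele
#'
#' Site-flanking pair: product = empty-site product + insert length, or no
#' product when that exceeds the amplifiable ceiling. Internal pair:
#' the internal product iff the allele contains the internal primer site.
#'
#' @param pair a [primer_pair()].
#' @param allele an [insertion_allele()].
#' @return product length in bp, or `NA_integer_` for no product.
#' @examples
#' pairs <- kit_primer_pairs()
#' predict_amplicon(pairs$AB, insertion_allele("IRISH_SOLITARY_LTR")) # 1590
#' predict_amplicon(pairs$AB, insertion_allele("HOODED_FULL_ERV"))   # NA
#' @export
predict_amplicon <- function(pair, allele) {
  stopifnot(inherits(pair, "primer_pair"),
            inherits(allele, "insertion_allele"))
  if (pair$requires_internal_site) {
    if (allele$contains_internal_primer_site)
      return(as.integer(pair$internal_product_bp))
    return(NA_integer_)
  }
  len <- pair$empty_site_product_bp + allele$insert_length_bp
  if (len > pair$max_amplifiable_bp) NA_integer_ else as.integer(len)
}

#' Infer insertion genotypes from observed PCR band patterns
#'
#' Inverts [predict_amplicon()]: enumerates all homozygous and heterozygous
#' allele combinations and keeps those whose predicted band pattern (union
#' of the two alleles' products per pair) matches every observed pattern
#' exactly. An empty consistent set is a conflict, with the per-genotype
#' violations listed.
#'
#' @param observed named list: pair name -> numeric vector of observed
#'   band sizes (`NULL`, `NA` or `numeric(0)` for no product).
#' @param pairs named list of [primer_pair()] (default
#'   [kit_primer_pairs()]).
#' @param alleles named list of [insertion_allele()] (default
#'   [hooded_alleles()]).
#' @return a `product_genotype` list: `genotypes` (data frame `allele1`,
#'   `allele2`, `label`), `conflict` flag, `violations`.
#' @examples
#' genotype_from_products(list(AB = 1590, CD = NULL))$genotypes$label
#' @export
genotype_from_products <- function(observed, pairs = kit_primer_pairs(),
                                   alleles = hooded_alleles()) {
  if (length(observed) == 0L) stop("products from at least one pair required")
  unknown <- setdiff(names(observed), names(pairs))
  if (length(unknown))
    stop("unknown primer pair(s): ", paste(unknown, collapse = ", "))
  norm <- function(x) sort(unique(as.numeric(x[!is.na(x)])))
  an <- names(alleles)
  combos <- expand.grid(a1 = seq_along(an), a2 = seq_along(an))
  combos <- combos[combos$a1 <= combos$a2, , drop = FALSE]
  rows <- list(); viol <- list()
  for (r in seq_len(nrow(combos))) {
    a1 <- alleles[[combos$a1[r]]]; a2 <- alleles[[combos$a2[r]]]
    ok <- TRUE
    for (p in names(observed)) {
      pred <- norm(c(predict_amplicon(pairs[[p]], a1),
                     predict_amplicon(pairs[[p]], a2)))
      obs <- norm(observed[[p]])
      if (!identical(pred, obs)) {
        ok <- FALSE
        viol[[length(viol) + 1L]] <- data.frame(
          allele1 = a1$name, allele2 = a2$name, pair = p,
          predicted = paste(pred, collapse = "+"),
          observed = paste(obs, collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
    if (ok)
      rows[[length(rows) + 1L]] <- data.frame(
        allele1 = a1$name, allele2 = a2$name,
        label = if (a1$name == a2$name) a1$name
                else paste(a1$name, a2$name, sep = "/"),
        stringsAsFactors = FALSE)
  }
  genotypes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(allele1 = character(), allele2 = character(),
               label = character(), stringsAsFactors = FALSE)
  structure(list(genotypes = genotypes,
                 conflict = nrow(genotypes) == 0L,
                 violations = if (nrow(genotypes) == 0L)
                   do.call(rbind, viol) else NULL),
            class = "product_genotype")
}
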