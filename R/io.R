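# TSV readers/writers for the three table formats. All plain text, exact
# round trip: write then read reproduces the object.

#' Read / write a marker map TSV
#'
#' Format: header `marker chrom pos_mb [pos_cm]`, tab-separated. When
#' `pos_cm` is absent it is derived at `cm_per_mb`.
#'
#' @param path file path.
#' @param cm_per_mb conversion rate used when the file has no `pos_cm`.
#' @return [read_genetic_map()]: a `genetic_map`.
#' @export
read_genetic_map <- function(path, cm_per_mb = 0.5) {
  df <- read_tsv_checked(path, c("marker", "chrom", "pos_mb"))
  genetic_map(df$marker, df$chrom, df$pos_mb,
              pos_cm = if ("pos_cm" %in% names(df)) df$pos_cm,
              cm_per_mb = cm_per_mb)
}

#' @rdname read_genetic_map
#' @param map a `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("marker", "chrom", "pos_mb",
                                            "pos_cm")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genotype matrix TSV
#'
#' Rows are animals, columns markers; first column `animal`; cells in
#' `C`, `H`, `N`, `-` (missing).
#'
#' @param path file path.
#' @return [read_genotypes()]: a `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_checked(path, "animal")
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "-"] <- NA_character_
  tryCatch(
    genotype_matrix(m, animal_ids = df$animal, marker_names = colnames(m)),
    error = function(e) stop("file ", path, ": ", conditionMessage(e),
                             call. = FALSE))
}

#' @rdname read_genotypes
#' @param genotypes a `genotype_matrix`.
#' @export
write_genotypes <- function(genotypes, path) {
  m <- unclass(genotypes)
  m[is.na(m)] <- "-"
  df <- data.frame(animal = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table TSV
#'
#' Format: header `animal anomaly side`; side `-` for unaffected animals.
#'
#' @param path file path.
#' @return [read_phenotypes()]: a `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path, c("animal", "anomaly", "side"))
  side <- df$side
  side[side == "-"] <- NA_character_
  phenotype_table(df$animal, df$anomaly, side)
}

#' @rdname read_phenotypes
#' @param phenotypes a `phenotype_table`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- data.frame(animal = phenotypes$animal_id,
                   anomaly = phenotypes$anomaly,
                   side = ifelse(is.na(phenotypes$side), "-",
                                 phenotypes$side),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (col in intersect(c("pos_mb", "pos_cm"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  df
}
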