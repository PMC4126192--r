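# Data model and I/O: genetic maps, RIL genotype matrices, phenotype tables.

#' Construct a genetic map
#'
#' A genetic map is an ordered table of markers with a chromosome assignment
#' and a position in centimorgans measured from the start of the chromosome.
#'
#' @param marker character vector of unique marker names.
#' @param chr chromosome identifier per marker (coerced to character);
#'   markers belonging to the same chromosome must be contiguous.
#' @param pos numeric position in cM, non-negative and strictly increasing
#'   within each chromosome.
#'
#' @return A data frame of class `"genmap"` with columns `marker`, `chr`,
#'   `pos`.
#' @export
#' @examples
#' genetic_map(c("m1", "m2", "m3"), c(1, 1, 2), c(0, 10.5, 0))
genetic_map <- function(marker, chr, pos) {
  marker <- as.character(marker)
  chr <- as.character(chr)
  pos <- as.numeric(pos)
  if (length(marker) == 0L)
    stop("a genetic map needs at least one marker")
  if (length(chr) != length(marker) || length(pos) != length(marker))
    stop("marker, chr and pos must have equal length")
  if (anyDuplicated(marker))
    stop("duplicate marker names: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(!is.finite(pos)) || any(pos < 0))
    stop("positions must be finite and >= 0 cM")
  if (any(duplicated(rle(chr)$values)))
    stop("markers of one chromosome must be contiguous in the map")
  for (cc in unique(chr)) {
    p <- pos[chr == cc]
    if (any(diff(p) <= 0))
      stop("positions on chromosome ", cc,
           " are not strictly increasing")
  }
  structure(data.frame(marker = marker, chr = chr, pos = pos,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("genmap", "data.frame"))
}

#' @export
print.genmap <- function(x, ...) {
  nchr <- length(unique(x$chr))
  cat("Genetic map: ", nrow(x), " markers on ", nchr,
      if (nchr == 1L) " chromosome\n" else " chromosomes\n", sep = "")
  len <- tapply(x$pos, x$chr, max)[unique(x$chr)]
  cat("  lengths (cM): ", paste(format(len, trim = TRUE), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Construct a RIL genotype matrix
#'
#' Binary genotypes for a biparental population: 0 for one parental type
#' (e.g. Bay), 1 for the other (e.g. Sha), `NA` for missing. Columns follow
#' the marker order of the map.
#'
#' @param geno integer/numeric matrix (lines x markers) over \{0, 1, NA\}.
#' @param map a [genetic_map()] whose markers match `colnames(geno)` (column
#'   names are set from the map when absent).
#' @param ril_ids line identifiers; defaults to `rownames(geno)` or
#'   `RIL1..RILn`.
#'
#' @return An object of class `"ril_geno"`: a list with elements `geno`
#'   (integer matrix) and `map`.
#' @export
ril_geno <- function(geno, map, ril_ids = NULL) {
  if (!inherits(map, "genmap")) stop("map must be a 'genmap'")
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map))
    stop("geno has ", ncol(geno), " columns but the map has ",
         nrow(map), " markers")
  bad <- !is.na(geno) & !(geno %in% c(0, 1))
  if (any(bad))
    stop("genotypes must be 0, 1 or missing; offending values: ",
         paste(utils::head(unique(geno[bad]), 5), collapse = ", "))
  storage.mode(geno) <- "integer"
  if (is.null(ril_ids)) ril_ids <- rownames(geno)
  if (is.null(ril_ids)) ril_ids <- paste0("RIL", seq_len(nrow(geno)))
  if (anyDuplicated(ril_ids)) stop("duplicate RIL ids")
  dimnames(geno) <- list(as.character(ril_ids), map$marker)
  structure(list(geno = geno, map = map), class = "ril_geno")
}

#' @export
print.ril_geno <- function(x, ...) {
  cat("RIL genotypes: ", nrow(x$geno), " lines x ", ncol(x$geno),
      " markers (", length(unique(x$map$chr)), " chromosomes)\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.ril_geno <- function(x) dim(x$geno)

.MISSING_CODES <- c("-", "NA", "", "9")

#' Read a genotype file
#'
#' Two dialects are supported. `"rqtl_csv"` is the R/qtl "csv" layout: row 1
#' holds an id column header plus marker names, rows 2 and 3 the chromosome
#' and cM position (blank in the id column), then one row per line with its
#' id and genotypes. `"plain_csv"` is a bare lines x markers matrix with a
#' header of marker names and row names in the first column; the map is
#' supplied separately as a 3-column CSV (`marker, chr, pos`) via `map_file`.
#'
#' Missing genotypes may be coded `-`, `NA`, `9` or an empty field; they are
#' always written back as `NA` by [write_genotypes()].
#'
#' @param path path to the genotype CSV.
#' @param dialect `"rqtl_csv"` (default) or `"plain_csv"`.
#' @param map_file map CSV, required for `dialect = "plain_csv"`.
#' @return A `"ril_geno"` object.
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, dialect = c("rqtl_csv", "plain_csv"),
                           map_file = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "rqtl_csv") {
    raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                           check.names = FALSE)
    if (nrow(raw) < 4L) stop("format error: need marker/chr/pos rows plus data")
    markers <- as.character(raw[1, -1])
    chr <- as.character(raw[2, -1])
    pos <- suppressWarnings(as.numeric(raw[3, -1]))
    if (any(is.na(pos))) stop("format error: non-numeric positions")
    map <- genetic_map(markers, chr, pos)
    body <- raw[-(1:3), , drop = FALSE]
    ids <- body[[1]]
    g <- as.matrix(body[, -1, drop = FALSE])
  } else {
    if (is.null(map_file)) stop("plain_csv dialect needs map_file")
    mp <- utils::read.csv(map_file, colClasses = c("character", "character",
                                                   "numeric"))
    map <- genetic_map(mp[[1]], mp[[2]], mp[[3]])
    raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
    ids <- raw[[1]]
    g <- as.matrix(raw[, -1, drop = FALSE])
    if (!identical(colnames(g), map$marker))
      stop("format error: genotype columns do not match the map markers")
  }
  g <- trimws(g)
  g[g %in% .MISSING_CODES] <- NA_character_
  bad <- !is.na(g) & !(g %in% c("0", "1"))
  if (any(bad))
    stop("format error: genotype entries must be 0/1/missing, found: ",
         paste(utils::head(unique(g[bad]), 5), collapse = ", "))
  gi <- matrix(as.integer(g), nrow = nrow(g))
  ril_geno(gi, map, ril_ids = ids)
}

#' Write a genotype file
#'
#' Inverse of [read_genotypes()]; round trips are lossless. Missing entries
#' are written as `NA`.
#'
#' @param x a `"ril_geno"` object.
#' @param path output CSV path.
#' @param dialect see [read_genotypes()].
#' @param map_file output map CSV path for `dialect = "plain_csv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, dialect = c("rqtl_csv", "plain_csv"),
                            map_file = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "ril_geno"))
  g <- x$geno
  gc <- matrix(as.character(g), nrow = nrow(g))
  gc[is.na(gc)] <- "NA"
  if (dialect == "rqtl_csv") {
    hdr <- rbind(c("id", x$map$marker),
                 c("", x$map$chr),
                 c("", format(x$map$pos, trim = TRUE, scientific = FALSE)))
    body <- cbind(rownames(g), gc)
    utils::write.table(rbind(hdr, body), path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    if (is.null(map_file)) stop("plain_csv dialect needs map_file")
    utils::write.csv(data.frame(marker = x$map$marker, chr = x$map$chr,
                                pos = x$map$pos), map_file, row.names = FALSE,
                     quote = FALSE)
    df <- data.frame(id = rownames(g), gc, check.names = FALSE)
    colnames(df) <- c("id", x$map$marker)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' One row per observation: a line id column, nuisance covariates, and trait
#' columns. Trait values may be missing (such rows are dropped by
#' [adjust_phenotypes()]).
#'
#' @param path CSV path with a header.
#' @param id_col name of the line-id column (default first column).
#' @return A plain data frame.
#' @export
read_phenotypes <- function(path, id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(id_col)) id_col <- names(df)[1]
  if (!id_col %in% names(df)) stop("id column not found: ", id_col)
  names(df)[names(df) == id_col] <- "ril_id"
  df$ril_id <- as.character(df$ril_id)
  df
}

#' Arabidopsis Bay-0 x Shahdara shaped genetic map (synthetic positions)
#'
#' A deterministic map with the published shape of the Bay-0 x Shahdara RIL
#' panel: 5 chromosomes of lengths 91.3, 64.6, 72.2, 69.1 and 91.2 cM
#' carrying 18, 11, 12, 11 and 17 markers (69 in total, mean adjacent
#' spacing 6.07 cM). Only the chromosome lengths and marker counts are
#' real; within each chromosome the first marker sits at 0 cM, the last at
#' the chromosome length, and the rest are evenly interpolated, so the
#' individual positions are synthetic stand-ins.
#'
#' @return A `"genmap"` with 69 markers.
#' @export
#' @examples
#' map <- arabidopsis_like_map()
#' mean(unlist(tapply(map$pos, map$chr, diff)))  # ~6.07 cM
arabidopsis_like_map <- function() {
  n_mark <- c(18L, 11L, 12L, 11L, 17L)
  len <- c(91.3, 64.6, 72.2, 69.1, 91.2)
  marker <- character(0); chr <- character(0); pos <- numeric(0)
  for (c_i in seq_along(n_mark)) {
    p <- seq(0, len[c_i], length.out = n_mark[c_i])
    marker <- c(marker, sprintf("C%dM%02d", c_i, seq_len(n_mark[c_i])))
    chr <- c(chr, rep(as.character(c_i), n_mark[c_i]))
    pos <- c(pos, p)
  }
  genetic_map(marker, chr, pos)
}
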