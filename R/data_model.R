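# Core data containers: linkage map, line-by-marker genotype matrix, trait
# table, and the dh_population bundle tying them together.

#' Construct a linkage map
#'
#' A linkage map is an ordered table of markers with chromosome assignment
#' and absolute position in centiMorgans within the chromosome.
#'
#' @param marker character vector of unique marker identifiers.
#' @param chromosome chromosome name per marker.
#' @param position_cM absolute position within chromosome, in cM (>= 0);
#'   must be non-decreasing within each chromosome in listed order.
#' @return A data frame of class `linkage_map` with columns `marker`,
#'   `chromosome`, `position_cM`.
#' @examples
#' linkage_map(c("M1", "M2", "M3"), c("1H", "1H", "2H"), c(0, 12.5, 0))
#' @export
linkage_map <- function(marker, chromosome, position_cM) {
  df <- data.frame(
    marker = as.character(marker),
    chromosome = as.character(chromosome),
    position_cM = as.numeric(position_cM),
    stringsAsFactors = FALSE
  )
  validate_linkage_map(df)
  class(df) <- c("linkage_map", "data.frame")
  df
}

#' Validate a linkage map table
#'
#' @param map data frame with columns `marker`, `chromosome`, `position_cM`.
#' @return The map, invisibly, if valid; otherwise an error.
#' @export
validate_linkage_map <- function(map) {
  need <- c("marker", "chromosome", "position_cM")
  miss <- setdiff(need, names(map))
  if (length(miss) > 0L) {
    te_stop("te_parse_error", "linkage map lacks column(s): ",
            paste(miss, collapse = ", "))
  }
  if (nrow(map) < 1L) te_stop("te_parse_error", "linkage map has no markers")
  dup <- map$marker[duplicated(map$marker)]
  if (length(dup) > 0L) {
    te_stop("te_parse_error", "duplicated marker id(s) in map: ",
            paste(unique(dup), collapse = ", "))
  }
  if (anyNA(map$position_cM) || any(map$position_cM < 0)) {
    te_stop("te_domain_error", "map positions must be finite and >= 0 cM")
  }
  for (chr in unique(map$chromosome)) {
    if (is.unsorted(map$position_cM[map$chromosome == chr])) {
      te_stop("te_parse_error",
              "positions not non-decreasing within chromosome ", chr)
    }
  }
  invisible(map)
}

#' Bundle genotypes, linkage map and phenotypes into a DH population
#'
#' @param geno numeric matrix, lines x markers; rownames are line ids,
#'   colnames are marker ids matching `map$marker`.  Entries are -1/+1
#'   (missing allowed as `NA`) before imputation, or values in `[-1, 1]`
#'   after flanking-marker imputation.
#' @param map a [linkage_map()].  Genotype columns are reordered to map
#'   order.
#' @param pheno optional data frame of trait values, one row per line
#'   (rownames are line ids), one numeric column per trait-by-environment
#'   set.  Column names of the form `"TRAIT.ENV"` are split at the first
#'   dot into trait and environment ids.
#' @return An object of class `dh_population`: a list with elements `map`,
#'   `geno` and `pheno`.
#' @export
dh_population <- function(geno, map, pheno = NULL) {
  validate_linkage_map(map)
  if (!is.matrix(geno) || !is.numeric(geno)) {
    te_stop("te_parse_error", "genotypes must be a numeric matrix")
  }
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    te_stop("te_parse_error", "genotype matrix needs line and marker names")
  }
  if (nrow(geno) < 2L) te_stop("te_domain_error", "need at least 2 lines")
  extra <- setdiff(colnames(geno), map$marker)
  if (length(extra) > 0L) {
    te_stop("te_alignment_error", "genotype marker(s) absent from map: ",
            paste(extra, collapse = ", "))
  }
  lost <- setdiff(map$marker, colnames(geno))
  if (length(lost) > 0L) {
    te_stop("te_alignment_error", "map marker(s) absent from genotypes: ",
            paste(lost, collapse = ", "))
  }
  geno <- geno[, map$marker, drop = FALSE]
  bad <- which(!is.na(geno) & (abs(geno) > 1))
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(geno)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(geno)) + 1L
    te_stop("te_coding_error", "genotype value ", geno[bad[1L]],
            " outside [-1, 1] at line ", rownames(geno)[i],
            ", marker ", colnames(geno)[j])
  }
  if (is.null(pheno)) {
    pheno <- data.frame(row.names = rownames(geno))
  }
  if (!identical(rownames(pheno), rownames(geno))) {
    te_stop("te_alignment_error",
            "phenotype lines do not match genotype lines")
  }
  structure(list(map = map, geno = geno, pheno = pheno),
            class = "dh_population")
}

#' @export
print.dh_population <- function(x, ...) {
  cat("DH population: ", nrow(x$geno), " lines, ", ncol(x$geno),
      " markers on ", length(unique(x$map$chromosome)), " chromosome(s), ",
      ncol(x$pheno), " trait set(s)\n", sep = "")
  nmiss <- sum(is.na(x$geno))
  if (nmiss > 0L) {
    cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nmiss,
                100 * nmiss / length(x$geno)))
  }
  invisible(x)
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_table <- function(path) {
  if (!file.exists(path)) te_stop("te_io_error", "file not found: ", path)
  out <- tryCatch(
    utils::read.table(path, header = TRUE, sep = .delim_for(path),
                      check.names = FALSE, colClasses = "character",
                      na.strings = c("NA", ".", ""), quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) {
      te_stop("te_parse_error", "malformed table ", path, ": ",
              conditionMessage(e))
    }
  )
  if (ncol(out) < 2L) {
    te_stop("te_parse_error", "table ", path,
            " needs an id column plus data columns")
  }
  out
}

.as_numeric_checked <- function(x, path, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    te_stop("te_parse_error", "non-numeric value \"", x[bad[1L]],
            "\" in ", what, " of ", path, " (row ", bad[1L], ")")
  }
  out
}

#' Read a DH population from genotype, map and phenotype files
#'
#' The genotype file is a line-by-marker table whose header row holds marker
#' ids and whose first column holds line ids; entries are -1/+1 with missing
#' values written as empty cells, `NA` or `.` (fractional imputed values in
#' `[-1, 1]` are also accepted).  The map file has columns `marker`,
#' `chromosome`, `position_cM`.  The phenotype file has a line-id column
#' followed by one numeric column per trait-by-environment set.  Delimiters
#' are inferred from the extension (`.csv` comma, otherwise tab).  Lines are
#' aligned across files by identifier; the genotype file order is canonical.
#'
#' @param genotype_path,map_path path to genotype / map table.
#' @param phenotype_path optional path to the phenotype table.
#' @return A [dh_population()].
#' @export
read_population <- function(genotype_path, map_path, phenotype_path = NULL) {
  graw <- .read_table(genotype_path)
  lines <- graw[[1L]]
  if (anyDuplicated(lines)) {
    te_stop("te_parse_error", "duplicated line id(s) in ", genotype_path)
  }
  geno <- as.matrix(vapply(
    graw[-1L],
    function(col) .as_numeric_checked(col, genotype_path, "genotype column"),
    numeric(nrow(graw))
  ))
  if (nrow(graw) == 1L) geno <- matrix(geno, nrow = 1L,
                                       dimnames = list(NULL, names(graw)[-1L]))
  rownames(geno) <- lines
  bad <- which(!is.na(geno) & abs(geno) > 1)
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(geno)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(geno)) + 1L
    te_stop("te_coding_error", "genotype value ", geno[bad[1L]],
            " outside {-1, 1, missing} at line ", rownames(geno)[i],
            ", marker ", colnames(geno)[j], " in ", genotype_path)
  }

  mraw <- .read_table(map_path)
  if (!"position_cM" %in% names(mraw) && "position" %in% names(mraw)) {
    names(mraw)[names(mraw) == "position"] <- "position_cM"
  }
  need <- c("marker", "chromosome", "position_cM")
  miss <- setdiff(need, names(mraw))
  if (length(miss) > 0L) {
    te_stop("te_parse_error", map_path, " lacks column(s): ",
            paste(miss, collapse = ", "))
  }
  map <- linkage_map(mraw$marker, mraw$chromosome,
                     .as_numeric_checked(mraw$position_cM, map_path,
                                         "position_cM"))

  pheno <- NULL
  if (!is.null(phenotype_path)) {
    praw <- .read_table(phenotype_path)
    pid <- praw[[1L]]
    extra <- setdiff(pid, lines)
    missing_lines <- setdiff(lines, pid)
    if (length(extra) > 0L || length(missing_lines) > 0L) {
      te_stop("te_alignment_error",
              "line ids differ between genotype and phenotype files;",
              if (length(extra) > 0L)
                paste0(" unknown: ", paste(extra, collapse = ", ")),
              if (length(missing_lines) > 0L)
                paste0(" absent: ", paste(missing_lines, collapse = ", ")))
    }
    vals <- lapply(names(praw)[-1L], function(nm) {
      .as_numeric_checked(praw[[nm]], phenotype_path,
                          paste0("trait column ", nm))
    })
    pheno <- as.data.frame(vals, col.names = names(praw)[-1L],
                           check.names = FALSE)
    rownames(pheno) <- pid
    pheno <- pheno[lines, , drop = FALSE]
  }
  dh_population(geno, map, pheno)
}

.format_geno <- function(v) {
  out <- character(length(v))
  out[is.na(v)] <- "NA"
  ok <- !is.na(v)
  whole <- ok & v == round(v)
  out[whole] <- as.character(as.integer(v[whole]))
  frac <- ok & !whole
  out[frac] <- sprintf("%.15g", v[frac])
  out
}

#' Write a DH population to disk
#'
#' Emits `genotypes.tsv`, `map.tsv` and `phenotypes.csv` in the formats
#' accepted by [read_population()].  Integer-coded genotypes round-trip
#' byte-identically; imputed fractional genotypes are serialized with 15
#' significant digits.
#'
#' @param pop a [dh_population()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_population <- function(pop, out_dir) {
  stopifnot(inherits(pop, "dh_population"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    te_stop("te_io_error", "cannot create directory ", out_dir)
  }
  gpath <- file.path(out_dir, "genotypes.tsv")
  mpath <- file.path(out_dir, "map.tsv")
  ppath <- file.path(out_dir, "phenotypes.csv")

  gchar <- apply(pop$geno, 2L, .format_geno)
  if (!is.matrix(gchar)) gchar <- matrix(gchar, nrow = nrow(pop$geno))
  gtab <- cbind(line = rownames(pop$geno), as.data.frame(gchar))
  names(gtab) <- c("line", colnames(pop$geno))
  utils::write.table(gtab, gpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(pop$map), mpath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ptab <- cbind(line = rownames(pop$pheno), pop$pheno)
  utils::write.table(ptab, ppath, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotypes = gpath, map = mpath, phenotypes = ppath))
}

#' Per-marker allele-coding report
#'
#' Counts +1, -1 and missing entries per marker and flags zero-variance
#' markers (all non-missing values equal).  Fractional imputed entries are
#' counted by sign; exact zeros count as neither allele.
#'
#' @param geno genotype matrix (lines x markers) or a [dh_population()].
#' @return Data frame with columns `marker`, `n_plus`, `n_minus`,
#'   `n_missing`, `zero_variance`.
#' @export
validate_coding <- function(geno) {
  if (inherits(geno, "dh_population")) geno <- geno$geno
  stopifnot(is.matrix(geno))
  res <- data.frame(
    marker = colnames(geno),
    n_plus = colSums(geno > 0, na.rm = TRUE),
    n_minus = colSums(geno < 0, na.rm = TRUE),
    n_missing = colSums(is.na(geno)),
    stringsAsFactors = FALSE
  )
  res$zero_variance <- apply(geno, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || length(unique(v)) == 1L
  })
  rownames(res) <- NULL
  res
}

# Split a phenotype column name into trait and environment ids at the
# first dot; names without a dot get an empty environment id.
.split_trait_id <- function(nm) {
  dot <- regexpr(".", nm, fixed = TRUE)
  if (dot < 0L) c(trait = nm, environment = "")
  else c(trait = substr(nm, 1L, dot - 1L),
         environment = substr(nm, dot + 1L, nchar(nm)))
}
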