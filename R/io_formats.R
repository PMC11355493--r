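#' Read a per-variant allele-count table
#'
#' Reads a tab-separated table of ultra-rare variant counts with header
#' columns `gene`, `variant`, `annotation`, `mpc`, `ac_case`, `ac_control`.
#' `annotation` is `PTV` or `missense`; `mpc` may be `NA` (typically for
#' PTVs, which are not scored). Allele counts must parse as non-negative
#' integers.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per variant and columns
#'   `gene`, `variant`, `annotation`, `mpc` (numeric, `NA` allowed),
#'   `ac_case`, `ac_control` (integer).
#' @seealso [write_variant_table()], [filter_ultra_rare()],
#'   [assign_variant_class()]
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) {
    stop("variant table not found: ", path)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""))
  required <- c("gene", "variant", "annotation", "mpc", "ac_case", "ac_control")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[required]
  if (nrow(tab) == 0) {
    tab$mpc <- numeric(0)
    tab$ac_case <- integer(0)
    tab$ac_control <- integer(0)
    return(tab)
  }
  parse_count <- function(x, col) {
    val <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad) > 0) {
      stop("column '", col, "' must hold non-negative integers; bad row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    as.integer(val)
  }
  tab$ac_case <- parse_count(tab$ac_case, "ac_case")
  tab$ac_control <- parse_count(tab$ac_control, "ac_control")
  tab$mpc <- suppressWarnings(as.numeric(tab$mpc))
  rownames(tab) <- NULL
  message(sprintf("[%s] read %d variant record(s) from %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), nrow(tab), path))
  tab
}

#' Write a per-variant allele-count table
#'
#' Inverse of [read_variant_table()]; writing then re-reading yields
#' identical field values.
#'
#' @param variants Data.frame as returned by [read_variant_table()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Retain ultra-rare variants
#'
#' Keeps variants whose combined case + control minor-allele count is between
#' 1 and `mac_max`. The default cap of 5 is the usual ultra-rare regime for
#' large exome case-control studies.
#'
#' @param variants Variant data.frame (needs `ac_case`, `ac_control`).
#' @param mac_max Maximum combined minor-allele count (default 5).
#' @return The retained rows, original order preserved.
#' @export
filter_ultra_rare <- function(variants, mac_max = 5) {
  stopifnot(mac_max >= 1)
  total <- variants$ac_case + variants$ac_control
  keep <- total >= 1 & total <= mac_max
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("[%s] ultra-rare filter (MAC <= %d): retained %d of %d variant(s)",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  mac_max, nrow(out), nrow(variants)))
  out
}

#' Assign variant classes from annotation and MPC score
#'
#' Protein-truncating variants and missense variants with a high MPC score
#' carry comparable burden and are pooled into class I; moderately damaging
#' missense variants form class II; missense variants below the lower MPC
#' bound are excluded. The intervals are half-open: class I missense is
#' `[mpc_high, Inf)` and class II is `[mpc_low, mpc_high)`, so a score equal
#' to `mpc_high` falls in class I.
#'
#' @param variants Variant data.frame (needs `annotation`, `mpc`).
#' @param mpc_high Lower MPC bound of class I missense (default 3).
#' @param mpc_low Lower MPC bound of class II missense (default 2).
#' @return The classified rows with an added `var_class` column (`"I"` or
#'   `"II"`); sub-threshold missense rows are dropped.
#' @export
assign_variant_class <- function(variants, mpc_high = 3, mpc_low = 2) {
  stopifnot(mpc_low < mpc_high)
  ann <- variants$annotation
  ok <- ann %in% c("PTV", "missense")
  if (!all(ok)) {
    stop("unknown annotation value(s): ",
         paste(unique(ann[!ok]), collapse = ", "))
  }
  is_mis <- ann == "missense"
  if (any(is_mis & is.na(variants$mpc))) {
    stop("missense variant(s) with missing mpc score; row(s): ",
         paste(utils::head(which(is_mis & is.na(variants$mpc)), 5),
               collapse = ", "))
  }
  var_class <- rep(NA_character_, nrow(variants))
  var_class[!is_mis] <- "I"
  var_class[is_mis & variants$mpc >= mpc_high] <- "I"
  var_class[is_mis & variants$mpc >= mpc_low & variants$mpc < mpc_high] <- "II"
  out <- variants[!is.na(var_class), , drop = FALSE]
  out$var_class <- var_class[!is.na(var_class)]
  rownames(out) <- NULL
  out
}

#' Read a gene set from a plain-text list
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored.
#' Symbols are upper-cased and deduplicated.
#'
#' @param path Path to the gene list.
#' @param name Label for the set (default: file base name).
#' @return A `gene_set` object: list with `name` and sorted `members`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop("gene set file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
           lines)
}

#' Construct a gene set
#'
#' @param name Label.
#' @param members Character vector of gene symbols; case-folded to upper and
#'   deduplicated.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, members) {
  structure(list(name = name,
                 members = sort(unique(toupper(as.character(members))))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d member(s)\n", x$name, length(x$members)))
  invisible(x)
}

#' Restrict a variant table to a gene set
#'
#' Keeps variants in genes belonging to the supplied set (typically the
#' constraint-gene universe, i.e. genes with pLI > 0.9). Symbols are
#' compared after upper-casing.
#'
#' @param variants Variant data.frame (needs `gene`).
#' @param constraint_set A `gene_set` or character vector of symbols.
#' @return The retained rows.
#' @export
restrict_to_gene_set <- function(variants, constraint_set) {
  members <- if (inherits(constraint_set, "gene_set")) {
    constraint_set$members
  } else {
    toupper(as.character(constraint_set))
  }
  keep <- toupper(variants$gene) %in% members
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0 && nrow(variants) > 0) {
    warning("no variants remain after gene-set restriction")
  }
  message(sprintf("[%s] gene-set restriction: %d of %d variant(s) in %d gene(s) retained",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  nrow(out), nrow(variants), length(unique(out$gene))))
  out
}
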