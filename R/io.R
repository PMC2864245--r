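## io_core: FASTA / GFF3 / Newick readers and writers plus the shared
## feature table.  Coordinates are 0-based half-open everywhere inside the
## package and converted to 1-based inclusive only at the GFF3 boundary.

#' IUPAC nucleotide alphabet accepted by [read_fasta()]
#' @keywords internal
.NT_ALPHABET <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                  "V", "H", "D", "B", "N")

#' Amino-acid alphabet (20 residues plus ambiguity/stop)
#' @keywords internal
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' GFF3 feature types used by the pipeline (Sequence Ontology names)
#' @keywords internal
.FEATURE_TYPES <- c("LTR_retrotransposon", "long_terminal_repeat",
                    "target_site_duplication", "ORF", "protein_domain",
                    "primer_binding_site", "RR_tract", "PCR_product")

#' Read a FASTA file
#'
#' Headers are split at the first whitespace into an identifier and a free
#' text description.  Residues are uppercased on read; for nucleotide input
#' `U` is converted to `T`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return A [Biostrings::DNAStringSet] (or [Biostrings::AAStringSet]) whose
#'   names are the record identifiers; descriptions are kept in
#'   `attr(x, "descriptions")` (named character vector).
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence record in ", path)
  if (alphabet == "nucleotide") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    bad <- !grepl(sprintf("^[%s]+$", paste(.NT_ALPHABET, collapse = "")), seqs)
    if (any(bad))
      stop("non-nucleotide characters in record(s): ",
           paste(ids[bad], collapse = ", "))
    out <- Biostrings::DNAStringSet(seqs)
  } else {
    bad <- !grepl("^[ARNDCQEGHILKMFPSTWYVXBZJU*-]+$", seqs)
    if (any(bad))
      stop("non-amino-acid characters in record(s): ",
           paste(ids[bad], collapse = ", "))
    out <- Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  attr(out, "descriptions") <- setNames(desc, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param x A named `XStringSet` or named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- as.character(x)
  ids <- names(seqs)
  if (is.null(ids) || any(ids == ""))
    stop("all sequences must be named")
  desc <- attr(x, "descriptions")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    hd <- ids[i]
    if (!is.null(desc) && !is.na(desc[ids[i]]) && nzchar(desc[ids[i]]))
      hd <- paste(hd, desc[ids[i]])
    writeLines(paste0(">", hd), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a feature table
#'
#' Features use 0-based half-open coordinates internally.  `attributes` is a
#' character vector in GFF3 `key=value;key=value` encoding (may be `""`).
#'
#' @param seqid,start,end,strand,type,attributes Vectors of equal length
#'   (recycled where length 1).
#' @return A `data.frame` with class `cm_features`.
#' @export
features <- function(seqid = character(), start = integer(), end = integer(),
                     strand = character(), type = character(),
                     attributes = "") {
  n <- max(length(seqid), length(start), length(end), length(type))
  if (n == 0L) {
    df <- data.frame(seqid = character(), start = integer(), end = integer(),
                     strand = character(), type = character(),
                     attributes = character(), stringsAsFactors = FALSE)
    class(df) <- c("cm_features", "data.frame")
    return(df)
  }
  df <- data.frame(seqid = rep_len(as.character(seqid), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   type = rep_len(as.character(type), n),
                   attributes = rep_len(as.character(attributes), n),
                   stringsAsFactors = FALSE)
  validate_features(df)
  class(df) <- c("cm_features", "data.frame")
  df
}

#' Validate a feature table
#'
#' Checks coordinate sanity, known types, and that strand is defined for all
#' types except target-site duplications.
#'
#' @param df A feature table.
#' @param seqlens Optional named vector of sequence lengths to check `end`
#'   against.
#' @return Invisibly, `df`.
#' @export
validate_features <- function(df, seqlens = NULL) {
  stopifnot(all(c("seqid", "start", "end", "strand", "type") %in% names(df)))
  if (any(df$start < 0L) || any(df$start >= df$end))
    stop("invalid feature coordinates: need 0 <= start < end")
  if (!all(df$type %in% .FEATURE_TYPES))
    stop("unknown feature type(s): ",
         paste(setdiff(df$type, .FEATURE_TYPES), collapse = ", "))
  need_strand <- df$type != "target_site_duplication"
  if (any(!(df$strand[need_strand] %in% c("+", "-"))))
    stop("strand must be '+' or '-' for all types except target_site_duplication")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (!is.null(seqlens)) {
    lim <- seqlens[df$seqid]
    if (any(is.na(lim)) || any(df$end > lim))
      stop("feature end beyond sequence length")
  }
  invisible(df)
}

#' Combine feature tables
#' @param ... Feature tables.
#' @return A single feature table.
#' @export
bind_features <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (length(dfs) == 0L) return(features())
  out <- do.call(rbind, lapply(dfs, as.data.frame))
  class(out) <- c("cm_features", "data.frame")
  out
}

#' Get one attribute value from GFF3-encoded attribute strings
#' @param df Feature table.
#' @param key Attribute key.
#' @return Character vector (NA where absent).
#' @export
feature_attr <- function(df, key) {
  m <- regmatches(df$attributes,
                  regexpr(sprintf("(?:^|;)%s=[^;]*", key), df$attributes))
  out <- rep(NA_character_, nrow(df))
  hit <- lengths(regmatches(df$attributes,
                            gregexpr(sprintf("(?:^|;)%s=", key),
                                     df$attributes))) > 0
  out[hit] <- sub(sprintf("^;?%s=", key), "", m)
  out
}

## internal <-> GFF3 coordinate conversion (its own inverse when composed)
to_gff3_coords <- function(start, end) list(start = start + 1L, end = end)
from_gff3_coords <- function(start, end) list(start = start - 1L, end = end)

#' Write features as GFF3
#'
#' Coordinates are emitted 1-based inclusive; rows are ordered
#' deterministically by (seqid, start, end, type).
#'
#' @param df Feature table (internal 0-based half-open coordinates).
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(df, path, source = "chromomine") {
  validate_features(df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df) > 0L) {
    ord <- order(df$seqid, df$start, df$end, df$type, method = "radix")
    df <- df[ord, , drop = FALSE]
    g <- to_gff3_coords(df$start, df$end)
    attrs <- ifelse(nzchar(df$attributes), df$attributes, ".")
    writeLines(paste(df$seqid, source, df$type, g$start, g$end, ".",
                     df$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path Path to a GFF3 file.
#' @return A feature table with internal 0-based half-open coordinates.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^##gff-version\\s+3", lines[1]))
    stop("not a GFF3 file (missing version pragma): ", path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) return(features())
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) stop("malformed GFF3 line in ", path)
  m <- do.call(rbind, fields)
  co <- from_gff3_coords(as.integer(m[, 4]), as.integer(m[, 5]))
  features(seqid = m[, 1], start = co$start, end = co$end,
           strand = m[, 7], type = m[, 3],
           attributes = ifelse(m[, 9] == ".", "", m[, 9]))
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are written with 6 significant digits; bootstrap supports
#' (if present in `tree$node.label`) become internal node labels.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}

#' Reverse-complement a nucleotide string
#' @param x Character scalar (IUPAC codes allowed).
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
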