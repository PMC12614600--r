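# Readers/writers for the on-disk formats the package touches.
#
# Residue indices are 1-based in PDB files (the standard) and 1-based
# internally too (idiomatic R); no index shifting happens at the boundary.

#' Read a FASTA file
#'
#' @param path file path.
#' @return named list mapping record id to uppercase sequence string.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA record without header at line 1")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    stop("FASTA record with empty sequence")
  }
  seqs <- toupper(gsub("\\s", "", seqs))
  bad <- regexpr(sprintf("[^%s]", paste0(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    ln <- which(hdr)[i]
    stop(sprintf("illegal residue character '%s' in record '%s' (header line %d)",
                 substr(seqs[i], bad[i], bad[i]), ids[i], ln))
  }
  stats::setNames(as.list(seqs), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named list/character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a minimal PDB file (ATOM records, one chain, one model)
#'
#' @param path file path.
#' @return data.frame with columns atom, res_index, res_name, element, x, y, z.
#' @export
read_pdb_min <- function(path) {
  lines <- readLines(path)
  keep <- grepl("^ATOM", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("no ATOM records in ", path)
  short <- nchar(lines) < 54
  if (any(short)) {
    stop(sprintf("truncated ATOM record at line %d", lineno[which(short)[1]]))
  }
  num <- function(s, from, to, what) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric %s at line %d", what, lineno[which(is.na(v))[1]]))
    }
    v
  }
  data.frame(
    atom = trimws(substr(lines, 13, 16)),
    res_name = trimws(substr(lines, 18, 20)),
    res_index = as.integer(num(lines, 23, 26, "residue index")),
    x = num(lines, 31, 38, "coordinate"),
    y = num(lines, 39, 46, "coordinate"),
    z = num(lines, 47, 54, "coordinate"),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
}

#' Write a structure as minimal PDB ATOM records
#'
#' Coordinates are written with 3 decimals (PDB precision).
#'
#' @param structure data.frame as returned by [read_pdb_min()].
#' @param path output path.
#' @export
write_pdb_min <- function(structure, path) {
  n <- nrow(structure)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n),
    ifelse(nchar(structure$atom) < 4, paste0(" ", structure$atom), structure$atom),
    structure$res_name, structure$res_index,
    structure$x, structure$y, structure$z, structure$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a typed tab-delimited table
#'
#' @param path file path.
#' @param schema named character vector: column name -> one of
#'   "integer", "real", "string", "int_list" (space-separated integers),
#'   "str_list" (comma-separated strings), "real_list".
#' @return data.frame; list columns for *_list types.
#' @export
read_table_schema <- function(path, schema) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!identical(colnames(df), names(schema))) {
    stop("schema mismatch: expected columns [",
         paste(names(schema), collapse = ", "), "], found [",
         paste(colnames(df), collapse = ", "), "]")
  }
  for (j in seq_along(schema)) {
    col <- df[[j]]
    df[[j]] <- switch(
      schema[[j]],
      string = col,
      integer = {
        v <- suppressWarnings(as.integer(col))
        if (any(is.na(v) & nzchar(col))) {
          stop(sprintf("column '%s': non-integer value '%s'",
                       names(schema)[j], col[which(is.na(v))[1]]))
        }
        v
      },
      real = {
        v <- suppressWarnings(as.numeric(col))
        if (any(is.na(v) & nzchar(col))) {
          stop(sprintf("column '%s': non-numeric value '%s'",
                       names(schema)[j], col[which(is.na(v))[1]]))
        }
        v
      },
      int_list = lapply(strsplit(col, " ", fixed = TRUE), function(s) {
        if (length(s) == 1 && !nzchar(s)) return(integer(0))
        v <- suppressWarnings(as.integer(s))
        if (any(is.na(v))) stop("non-integer entry in int_list cell")
        v
      }),
      real_list = lapply(strsplit(col, " ", fixed = TRUE), function(s) {
        if (length(s) == 1 && !nzchar(s)) return(numeric(0))
        v <- suppressWarnings(as.numeric(s))
        if (any(is.na(v))) stop("non-numeric entry in real_list cell")
        v
      }),
      str_list = lapply(strsplit(col, ",", fixed = TRUE), function(s) {
        s[nzchar(s)]
      }),
      stop("unknown schema type: ", schema[[j]])
    )
  }
  df
}

#' Write a typed table (inverse of [read_table_schema()])
#'
#' @param df data.frame (list columns allowed).
#' @param path output path.
#' @param schema schema used to serialize list columns.
#' @export
write_table_schema <- function(df, path, schema) {
  out <- df
  for (j in seq_along(schema)) {
    ty <- schema[[j]]
    if (ty %in% c("int_list", "real_list")) {
      out[[j]] <- vapply(df[[j]], function(v) paste(format(v, scientific = FALSE, trim = TRUE), collapse = " "), "")
    } else if (ty == "str_list") {
      out[[j]] <- vapply(df[[j]], paste, "", collapse = ",")
    } else if (ty == "real") {
      out[[j]] <- format(df[[j]], digits = 17, scientific = FALSE, trim = TRUE)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an embedding container (delimited text)
#'
#' Full 17-significant-digit precision keeps round trips lossless within
#' double precision.
#'
#' @param embeddings numeric matrix with rownames = protein ids.
#' @param path output path.
#' @param modality modality tag stored in the header.
#' @param model model tag stored in the header.
#' @export
write_embeddings <- function(embeddings, path, modality = "unknown",
                             model = "modalign") {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  if (anyDuplicated(rownames(embeddings))) stop("duplicate embedding ids")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#dim\t%d\t%s\t%s", ncol(embeddings), modality, model), con)
  rows <- apply(embeddings, 1, function(v) {
    paste(sprintf("%.17g", v), collapse = "\t")
  })
  writeLines(paste(rownames(embeddings), rows, sep = "\t"), con)
  invisible(path)
}

#' Read an embedding container written by [write_embeddings()]
#'
#' @param path file path.
#' @return numeric matrix with rownames; attributes `modality` and `model`.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "#dim") stop("missing embedding header")
  l <- as.integer(hdr[2])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  dims <- lengths(body)
  if (any(dims != l + 1)) {
    stop(sprintf("dimension mismatch at row %d: expected %d values",
                 which(dims != l + 1)[1], l))
  }
  ids <- vapply(body, `[`, "", 1)
  M <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1])))
  rownames(M) <- ids
  attr(M, "modality") <- hdr[3]
  attr(M, "model") <- hdr[4]
  M
}
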