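#' Construct an AssociationMatrix from a plain matrix
#'
#' @param values numeric matrix with microbe row names and disease column
#'   names. Binary stage requires entries in {0, 1}.
#' @param stage \code{"binary"} (default) or \code{"wknkn"}.
#' @param nDuplicates integer bookkeeping: duplicate edges collapsed on load.
#' @return An \linkS4class{AssociationMatrix}.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("m1", "m2"), c("d1", "d2")))
#' associationMatrix(m)
#' @export
associationMatrix <- function(values, stage = "binary", nDuplicates = 0L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("AssociationMatrix", values, stage = stage,
      nDuplicates = as.integer(nDuplicates))
}

#' Read a microbe-disease association edge list
#'
#' Reads a two-column delimited file (microbe label, disease label; one row
#' per curated association), collapses duplicate edges, and builds the binary
#' adjacency matrix. Entity order is first appearance in the file; labels are
#' whitespace-trimmed and matched case-sensitively.
#'
#' @param path path to the edge-list file.
#' @param delimiter field delimiter, default tab.
#' @param comment lines starting with this character are skipped; default "#".
#' @return A binary-stage \linkS4class{AssociationMatrix}; the number of
#'   duplicate edges removed is available via \code{nDuplicatesRemoved()}.
#' @examples
#' f <- tempfile()
#' writeLines(c("m1\td1", "m1\td1", "m2\td2"), f)
#' A <- readEdgeList(f)
#' nDuplicatesRemoved(A)  # 1
#' @export
readEdgeList <- function(path, delimiter = "\t", comment = "#") {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(trimws(lines), comment)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no associations in ", path)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    stop("malformed row (need >= 2 fields) at line ", lineno[bad[1L]],
         " of ", path)
  microbe <- trimws(vapply(parts, `[[`, "", 1L))
  disease <- trimws(vapply(parts, `[[`, "", 2L))
  empty <- which(microbe == "" | disease == "")
  if (length(empty))
    stop("empty entity label at line ", lineno[empty[1L]], " of ", path)
  dup <- duplicated(paste(microbe, disease, sep = "\r"))
  nDup <- sum(dup)
  microbe <- microbe[!dup]
  disease <- disease[!dup]
  mNames <- unique(microbe)
  dNames <- unique(disease)
  A <- matrix(0, length(mNames), length(dNames),
              dimnames = list(mNames, dNames))
  A[cbind(match(microbe, mNames), match(disease, dNames))] <- 1
  associationMatrix(A, stage = "binary", nDuplicates = nDup)
}

#' @rdname readEdgeList
#' @param x an \linkS4class{AssociationMatrix} built by \code{readEdgeList}.
#' @export
nDuplicatesRemoved <- function(x) x@nDuplicates

#' Write / read an AssociationMatrix as headered TSV
#'
#' Serializes the matrix as tab-delimited text with disease names in the
#' header row and microbe names in the first column, preceded by a single
#' comment line recording the processing stage. \code{readAssociationMatrix}
#' inverts it exactly: values and both name indexes round-trip.
#'
#' @param A an \linkS4class{AssociationMatrix}.
#' @param path output (input) file path.
#' @return \code{writeAssociationMatrix} returns \code{path} invisibly;
#'   \code{readAssociationMatrix} returns the \linkS4class{AssociationMatrix}.
#' @examples
#' A <- associationMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' f <- tempfile()
#' writeAssociationMatrix(A, f)
#' identical(unname(readAssociationMatrix(f)@.Data), unname(A@.Data))
#' @export
writeAssociationMatrix <- function(A, path) {
  stopifnot(is(A, "AssociationMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# latentMDA AssociationMatrix stage=%s", A@stage), con)
  writeLines(paste(c("microbe", colnames(A)), collapse = "\t"), con)
  body <- apply(A@.Data, 1L, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(paste(rownames(A), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeAssociationMatrix
#' @export
readAssociationMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  stg <- sub(".*stage=", "", first)
  if (!stg %in% c("binary", "wknkn")) stg <- "binary"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  associationMatrix(m, stage = stg)
}
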