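# File formats: CASP RR contact predictions, pair-list truth files and
# structure-derived native contact maps.

#' Read a CASP RR contact prediction file
#'
#' Parses the CASP RR dialect: whitespace-separated records
#' `i j d_low d_high prob`, with optional `PFRMAT`/`TARGET`/`AUTHOR`/
#' `METHOD`/`MODEL`/`REMARK`/`END` header lines and optional sequence lines,
#' all of which are skipped.  Bare three-column `i j prob` score tables are
#' accepted as well.  Pairs are canonicalized to `i < j`; duplicate pairs
#' keep the highest confidence.
#'
#' @param path path to the RR file.
#' @param protein_id protein identifier to attach (default: file stem, or the
#'   TARGET header when present).
#' @param method_id predictor identifier to attach (default: file stem).
#' @return a [prediction_set()].
#' @examples
#' f <- tempfile(fileext = ".rr")
#' writeLines(c("PFRMAT RR", "1 9 0 8 0.73", "END"), f)
#' read_rr(f, "toy", "mA")
#' @export
read_rr <- function(path, protein_id = NULL, method_id = NULL) {
  if (!file.exists(path)) stop("RR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stem <- sub("\\.[^.]*$", "", basename(path))
  target <- NULL
  i <- integer(0); j <- integer(0); conf <- numeric(0)
  header_re <- "^(PFRMAT|AUTHOR|METHOD|MODEL|REMARK|END|RMODE)\\b"
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (grepl("^TARGET\\b", line)) {
      target <- trimws(sub("^TARGET", "", line))
      next
    }
    if (grepl(header_re, line)) next
    if (grepl("^[A-Za-z]+$", line)) next  # sequence line
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (!(length(tok) %in% c(3L, 5L))) {
      stop(sprintf("line %d of %s: expected 3 or 5 fields, got %d",
                   ln, path, length(tok)))
    }
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals)) {
      stop(sprintf("line %d of %s: malformed numeric field", ln, path))
    }
    ii <- vals[1]; jj <- vals[2]
    if (ii != round(ii) || jj != round(jj)) {
      stop(sprintf("line %d of %s: residue indices must be integers", ln, path))
    }
    if (ii == jj) {
      stop(sprintf("line %d of %s: rejected record with i == j", ln, path))
    }
    i <- c(i, as.integer(ii)); j <- c(j, as.integer(jj))
    conf <- c(conf, vals[length(vals)])
  }
  prediction_set(
    protein_id = protein_id %||% target %||% stem,
    method_id = method_id %||% stem,
    pairs = cbind(i, j), confidence = conf, dedupe = "max"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a prediction set as a CASP RR file
#'
#' Emits `PFRMAT RR`, `TARGET`, `MODEL 1`, one record `i j 0 8 prob` per
#' pair sorted by decreasing confidence (ties by increasing i, then j), and
#' `END`.  `read_rr(write_rr(x))` reproduces pairs and confidences to the
#' printed precision (6 decimals).
#'
#' @param predictions a [prediction_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(predictions, path) {
  stopifnot(inherits(predictions, "prediction_set"))
  e <- predictions$entries
  if (anyNA(e$confidence) || any(is.nan(e$confidence))) {
    stop("cannot write RR file: NaN confidence")
  }
  ord <- order(-e$confidence, e$i, e$j)
  e <- e[ord, , drop = FALSE]
  lines <- c(
    "PFRMAT RR",
    paste("TARGET", predictions$protein_id),
    "MODEL 1",
    if (nrow(e) > 0) sprintf("%d %d 0 8 %.6f", e$i, e$j, e$confidence),
    "END"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a pair-list truth file
#'
#' Format: a header line `L <int>` followed by one `i j` pair per line.
#' Pairs are canonicalized and deduplicated; a pair with `j > L` is an
#' error.
#'
#' @param path path to the pair-list file.
#' @param protein_id protein identifier (default: file stem).
#' @param min_separation minimum sequence separation recorded on the map.
#' @return a [contact_map()].
#' @export
read_pair_list <- function(path, protein_id = NULL, min_separation = 6L) {
  if (!file.exists(path)) stop("pair-list file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0 || !grepl("^L[[:space:]]+[0-9]+$", lines[1])) {
    stop("pair-list file must start with a header 'L <int>': ", path)
  }
  L <- as.integer(strsplit(lines[1], "[[:space:]]+")[[1]][2])
  body <- lines[-1]
  if (length(body) > 0) {
    tok <- strsplit(body, "[[:space:]]+")
    bad <- which(vapply(tok, length, 1L) != 2L)
    if (length(bad)) stop("malformed pair line in ", path, " (line ", bad[1] + 1, ")")
    i <- as.integer(vapply(tok, `[`, "", 1L))
    j <- as.integer(vapply(tok, `[`, "", 2L))
    if (anyNA(i) || anyNA(j)) stop("malformed pair indices in ", path)
    if (any(pmax(i, j) > L)) stop("pair with index > L in ", path)
    pairs <- canonical_pairs(i, j)
  } else {
    pairs <- matrix(integer(0), ncol = 2)
  }
  contact_map(protein_id %||% sub("\\.[^.]*$", "", basename(path)),
              L = L, contacts = pairs, min_separation = min_separation)
}

#' Write a contact map as a pair-list truth file
#'
#' @param map a [contact_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_list <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  lines <- c(paste("L", map$L),
             if (nrow(map$contacts) > 0) {
               sprintf("%d %d", map$contacts[, 1], map$contacts[, 2])
             })
  writeLines(lines, path)
  invisible(path)
}

#' Derive a native contact map from a PDB structure
#'
#' Two residues are in contact when the distance between their Cbeta atoms
#' (Calpha when Cbeta is absent, e.g. glycine) is at most `threshold`
#' Angstrom and their sequence separation is at least `min_separation`.
#' This Cbeta definition with an 8 A threshold and separation >= 6 is the
#' prevailing convention in CASP-style contact evaluation.  Residues with
#' neither atom are skipped with a warning.  Only the first model of the
#' file is used; residues with insertion codes are renumbered sequentially.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier.
#' @param threshold contact distance threshold in Angstrom.
#' @param min_separation minimum sequence separation of a contact.
#' @return a [contact_map()] with `L` = highest observed residue index.
#' @export
contacts_from_structure <- function(path, chain, threshold = 8,
                                    min_separation = 6L) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE),
                  error = function(e) stop("unreadable structure file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$chain %in% chain & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found in ", path)
  # drop alternate locations beyond the first
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ins <- at$insert %||% rep("", nrow(at))
  ins[is.na(ins)] <- ""
  res_key <- paste(at$resno, ins, sep = "|")
  res_order <- unique(res_key)
  has_insert <- any(nzchar(trimws(ins)))
  resno_map <- if (has_insert) {
    stats::setNames(seq_along(res_order), res_order)
  } else {
    stats::setNames(as.integer(sub("\\|.*$", "", res_order)), res_order)
  }
  coords <- matrix(NA_real_, nrow = length(res_order), ncol = 3)
  skipped <- character(0)
  for (k in seq_along(res_order)) {
    rows <- at[res_key == res_order[k], , drop = FALSE]
    cb <- rows[rows$elety == "CB", , drop = FALSE]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    use <- if (nrow(cb) > 0) cb[1, ] else if (nrow(ca) > 0) ca[1, ] else NULL
    if (is.null(use) || anyNA(c(use$x, use$y, use$z))) {
      skipped <- c(skipped, res_order[k])
      next
    }
    coords[k, ] <- c(use$x, use$y, use$z)
  }
  if (length(skipped)) {
    warning(length(skipped), " residue(s) lacking CB and CA atoms skipped in ",
            basename(path))
  }
  resno <- unname(resno_map[res_order])
  ok <- !is.na(coords[, 1])
  coords <- coords[ok, , drop = FALSE]
  resno <- resno[ok]
  if (length(resno) == 0) stop("no usable coordinates in chain '", chain, "'")
  L <- max(resno)
  d <- as.matrix(stats::dist(coords))
  sep <- abs(outer(resno, resno, "-"))
  hit <- which(d <= threshold & sep >= min_separation & upper.tri(d),
               arr.ind = TRUE)
  pairs <- if (nrow(hit) > 0) {
    canonical_pairs(resno[hit[, 1]], resno[hit[, 2]])
  } else {
    matrix(integer(0), ncol = 2)
  }
  contact_map(sub("\\.[^.]*$", "", basename(path)), L = L, contacts = pairs,
              min_separation = min_separation, distance_threshold = threshold)
}
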