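#' Read protein sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet} with the
#' validation this toolkit needs: every record must have a non-empty id
#' and a non-empty sequence, and in strict mode every residue must be one
#' of the 20 standard amino acids (lenient mode keeps X/B/Z/U etc., which
#' downstream PSEE computation marks unavailable).
#'
#' @param path FASTA file path
#' @param strict reject records containing non-standard residue codes
#' @return a named \code{AAStringSet}
#' @export
readFasta <- function(path, strict = FALSE) {
    if (!file.exists(path)) .stopf("FASTA file not found: '%s'", path)
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L) .stopf("no FASTA records in '%s'", path)
    ids <- names(seqs)
    if (any(!nzchar(ids)))
        .stopf("record %d in '%s' has an empty id",
               which(!nzchar(ids))[1L], path)
    empty <- Biostrings::width(seqs) == 0L
    if (any(empty))
        .stopf("record '%s' in '%s' has an empty sequence",
               ids[which(empty)[1L]], path)
    if (strict) {
        for (i in seq_along(seqs)) {
            res <- .residues(as.character(seqs[[i]]))
            bad <- setdiff(unique(res), AA_STANDARD)
            if (length(bad))
                .stopf("record '%s': non-standard residue(s) %s",
                       ids[i], paste(bad, collapse = ", "))
        }
    }
    seqs
}

#' Write sequences to FASTA
#'
#' @param seqs a named \code{AAStringSet} (or named character vector)
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
writeFasta <- function(seqs, path) {
    if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

.TRACK_ALPHABETS <- list(disorder = c("O", "D", "X"),
                         secondary = c("H", "E", "C"))

#' Read per-residue annotation tracks
#'
#' Accepts either a FASTA-like layout (\code{>seq_id} headers followed by
#' symbol lines) holding one track per sequence, or a bare positional
#' layout (symbols only, one track). Symbols are validated against the
#' chosen alphabet: \code{"disorder"} = O (ordered), D (disordered),
#' X (unknown); \code{"secondary"} = H (helix), E (beta), C (coil). An
#' optional symbol mapping converts other annotation dialects first.
#'
#' @param path annotation file path
#' @param alphabet \code{"disorder"} (default) or \code{"secondary"}
#' @param map optional named character vector mapping foreign symbols to
#'   alphabet symbols, e.g. \code{c("-" = "O", "1" = "D")}
#' @param sequences optional named \code{AAStringSet}; when given, every
#'   track is checked to match its sequence's length
#' @return named list of per-residue symbol character vectors
#' @export
readAnnotation <- function(path, alphabet = c("disorder", "secondary"),
                           map = NULL, sequences = NULL) {
    alphabet <- match.arg(alphabet)
    ok <- .TRACK_ALPHABETS[[alphabet]]
    if (!file.exists(path)) .stopf("annotation file not found: '%s'", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) .stopf("annotation file '%s' is empty", path)
    tracks <- list()
    if (startsWith(lines[1L], ">")) {
        id <- NULL; buf <- character()
        flush <- function() {
            if (!is.null(id)) tracks[[id]] <<- paste(buf, collapse = "")
        }
        for (ln in lines) {
            if (startsWith(ln, ">")) {
                flush()
                id <- trimws(sub("^>", "", ln)); buf <- character()
                if (!nzchar(id)) .stopf("empty track id in '%s'", path)
            } else buf <- c(buf, gsub("[[:space:]]", "", ln))
        }
        flush()
    } else {
        tracks[["track1"]] <- paste(gsub("[[:space:]]", "", lines),
                                    collapse = "")
    }
    out <- lapply(names(tracks), function(id) {
        sym <- toupper(strsplit(tracks[[id]], "", fixed = TRUE)[[1L]])
        if (!is.null(map)) {
            hit <- sym %in% names(map)
            sym[hit] <- unname(map[sym[hit]])
        }
        bad <- setdiff(unique(sym), ok)
        if (length(bad))
            .stopf("track '%s': symbol(s) %s outside alphabet {%s}", id,
                   paste(bad, collapse = ", "), paste(ok, collapse = ","))
        sym
    })
    names(out) <- names(tracks)
    if (!is.null(sequences)) {
        for (id in names(out)) {
            if (!id %in% names(sequences))
                .stopf("track '%s' has no matching sequence", id)
            want <- Biostrings::width(sequences[id])
            if (length(out[[id]]) != want)
                .stopf("track '%s' length %d does not match sequence length %d",
                       id, length(out[[id]]), want)
        }
    }
    out
}

#' Read per-residue predicted ASA values
#'
#' Accepts either bare one-value-per-line text (positional) or
#' two-column (position, value) text; positions may appear in any order
#' but must cover 1..L exactly once. Values are surface areas in squared
#' angstroms and must be finite and non-negative.
#'
#' @param path ASA file path
#' @param length expected number of residues L
#' @return numeric vector of L ASA values in position order
#' @export
readASA <- function(path, length) {
    if (!file.exists(path)) .stopf("ASA file not found: '%s'", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\r$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!base::length(lines)) .stopf("ASA file '%s' is empty", path)
    fields <- strsplit(lines, "[[:space:],\t]+")
    nf <- lengths(fields)
    if (all(nf == 1L)) {
        vals <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
        pos <- seq_along(vals)
    } else if (all(nf == 2L)) {
        pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1L)))
        vals <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
        if (any(is.na(pos)))
            .stopf("ASA file '%s': non-integer position on line %d", path,
                   which(is.na(pos))[1L])
    } else {
        .stopf("ASA file '%s': mixed 1- and 2-column layout (line %d)",
               path, which(nf != nf[1L])[1L])
    }
    if (any(is.na(vals)))
        .stopf("ASA file '%s': non-numeric value on line %d", path,
               which(is.na(vals))[1L])
    if (any(vals < 0))
        .stopf("ASA file '%s': negative area at position %d", path,
               pos[which(vals < 0)[1L]])
    if (base::length(vals) != length || !setequal(pos, seq_len(length)))
        .stopf("ASA file '%s': expected positions 1..%d, got %d value(s)",
               path, length, base::length(vals))
    vals[order(pos)]
}

#' Write a per-residue results table
#'
#' Tab-delimited text with one row per residue: seq_id, position, aa,
#' asa, p_exp, p_bur, psee and, when predictions are supplied, raw_prob,
#' rescaled_prob and label. Floating-point columns are written at 4
#' decimals; unavailable values as \code{NA}.
#'
#' @param profiles a profile data.frame from \code{\link{residueProfile}}
#'   (a \code{seq_id} column is added if absent)
#' @param path output file path
#' @param predictions optional data.frame from
#'   \code{\link{predictDisorder}}, aligned row-for-row
#' @param seqId id used when \code{profiles} lacks a seq_id column
#' @return invisibly, \code{path}
#' @export
writeResidueTable <- function(profiles, path, predictions = NULL,
                              seqId = "seq1") {
    df <- profiles
    if (is.null(df$seq_id)) df <- cbind(seq_id = seqId, df)
    if (!is.null(predictions)) {
        stopifnot(nrow(predictions) == nrow(df))
        df <- cbind(df, predictions)
    }
    num <- vapply(df, is.numeric, TRUE) & !names(df) %in% c("position")
    df[num] <- lapply(df[num], function(x) formatC(x, format = "f",
                                                   digits = 4L))
    df[num] <- lapply(df[num], function(x) ifelse(grepl("NA", x), "NA", x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a per-residue results table written by writeResidueTable
#'
#' @param path table file path
#' @return data.frame
#' @export
readResidueTable <- function(path) {
    if (!file.exists(path)) .stopf("residue table not found: '%s'", path)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write predictor metric tables
#'
#' Delimited text with a predictor column plus the four metric columns
#' acc, ppv, mcc, auc; \code{writeMetricTable} also accepts the ranked
#' table from \code{\link{rankPredictors}} and keeps its appended
#' columns.
#'
#' @param path file path
#' @return \code{readMetricTable}: data.frame
#' @export
readMetricTable <- function(path) {
    if (!file.exists(path)) .stopf("metric table not found: '%s'", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    need <- c("predictor", "acc", "ppv", "mcc", "auc")
    miss <- setdiff(need, names(df))
    if (length(miss))
        .stopf("metric table '%s' lacks column(s): %s", path,
               paste(miss, collapse = ", "))
    df
}

#' @rdname readMetricTable
#' @param table data.frame of metrics (optionally ranked)
#' @export
writeMetricTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
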