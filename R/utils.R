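# internal validation helpers

# Normalize amino-acid codes to uppercase; reject anything outside the
# 20-letter alphabet (X, B, Z, U, ...) rather than imputing.
.checkAA <- function(aa, context = "amino acid") {
    aa <- toupper(as.character(aa))
    bad <- setdiff(unique(aa), AA_STANDARD)
    if (length(bad))
        stop(sprintf("non-standard %s code(s): %s", context,
                     paste(bad, collapse = ", ")), call. = FALSE)
    aa
}

# Split a sequence (string or character vector) into single residues,
# uppercased, without alphabet validation.
.residues <- function(sequence) {
    if (length(sequence) == 1L && nchar(sequence[1L]) > 1L)
        sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    toupper(as.character(sequence))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
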