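# sequence helpers; dictionaries may be RNA, reads DNA, so everything is
# normalized to DNA space (U -> T) before comparison

.dnaNorm <- function(x) {
    x <- toupper(x)
    gsub("U", "T", x, fixed = TRUE)
}

.checkAlphabet <- function(x, what = "sequence") {
    bad <- grepl("[^ACGTU]", toupper(x))
    if (any(bad))
        stop(sprintf("%s contains characters outside the A/C/G/T/U alphabet",
                     what), call. = FALSE)
    invisible(TRUE)
}

.revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(.dnaNorm(x))))
}

.randomDna <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""),
        character(1))
}

# phred+33 helpers for FASTQ synthesis / filtering
.phredToChar <- function(q) {
    rawToChar(as.raw(q + 33L))
}

.charToPhred <- function(s) {
    lapply(s, function(x) as.integer(charToRaw(x)) - 33L)
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                          strictLower = FALSE, strictUpper = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single number", name), call. = FALSE)
    if (strictLower && x <= lower)
        stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
    if (!strictLower && x < lower)
        stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
    if (strictUpper && x >= upper)
        stop(sprintf("'%s' must be < %g", name, upper), call. = FALSE)
    if (!strictUpper && x > upper)
        stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
    invisible(TRUE)
}

.withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    withr::with_seed(as.integer(seed), code)
}

# two-group design: named character vector, values "KO"/"control"
.checkDesign <- function(design, samples = NULL, requireThreeEach = FALSE) {
    if (is.null(names(design)) || anyDuplicated(names(design)))
        stop("design must be a character vector named by unique sample names",
             call. = FALSE)
    if (!all(design %in% c("KO", "control")))
        stop("design values must be 'KO' or 'control'", call. = FALSE)
    if (length(unique(design)) != 2L)
        stop("design must contain exactly two groups (KO and control)",
             call. = FALSE)
    if (!is.null(samples) && !setequal(names(design), samples))
        stop("design sample names must match the count table samples",
             call. = FALSE)
    if (requireThreeEach && !all(table(design) == 3L))
        stop("design must have 3 KO and 3 control samples", call. = FALSE)
    invisible(TRUE)
}
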