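#' Construct a MirnaDictionary
#'
#' @param name character vector of unique species names.
#' @param sequence miRNA sequences (RNA or DNA alphabet; stored as DNA).
#' @param hairpinId hairpin of origin for each species.
#' @param arm \code{"5p"} or \code{"3p"} for each species.
#' @param role \code{"mature"} or \code{"passenger"} for each species.
#' @param variantOf optional parent species name for processing variants.
#' @param context3p templated 3' hairpin context appended when isoforms
#'   longer than the reference sequence are synthesized (may be \code{""}).
#' @return a \linkS4class{MirnaDictionary}.
#' @export
MirnaDictionary <- function(name, sequence, hairpinId, arm, role,
                            variantOf = NA_character_, context3p = "") {
    .checkAlphabet(sequence, "dictionary sequence")
    n <- length(name)
    sp <- DataFrame(
        name = as.character(name),
        sequence = .dnaNorm(sequence),
        hairpin_id = rep_len(as.character(hairpinId), n),
        arm = rep_len(as.character(arm), n),
        role = rep_len(as.character(role), n),
        variant_of = rep_len(as.character(variantOf), n),
        context3p = .dnaNorm(rep_len(as.character(context3p), n)))
    new("MirnaDictionary", species = sp)
}

#' @describeIn MirnaDictionary species table accessor.
#' @param x,object a \code{MirnaDictionary}.
#' @export
mirnaSpecies <- function(x) x@species

#' @describeIn MirnaDictionary species names.
#' @export
mirnaNames <- function(x) x@species$name

#' @describeIn MirnaDictionary sequences as a named
#'   \link[Biostrings]{DNAStringSet}.
#' @export
mirnaSequences <- function(x) {
    s <- Biostrings::DNAStringSet(x@species$sequence)
    names(s) <- x@species$name
    s
}

setMethod("show", "MirnaDictionary", function(object) {
    sp <- object@species
    cat(sprintf("MirnaDictionary with %d species (%d mature, %d passenger) from %d hairpins\n",
                nrow(sp), sum(sp$role == "mature"),
                sum(sp$role == "passenger"),
                length(unique(sp$hairpin_id))))
    if (nrow(sp)) show(head(sp, 4L))
})

#' Map each mature species to its passenger species
#'
#' Passengers are species with \code{role == "passenger"} sharing a
#' \code{hairpin_id} with the mature species.
#'
#' @param dict a \linkS4class{MirnaDictionary}.
#' @return named list: mature name -> character vector of passenger names
#'   (possibly empty).
#' @export
passengerMap <- function(dict) {
    sp <- mirnaSpecies(dict)
    mat <- sp[sp$role == "mature", , drop = FALSE]
    pas <- sp[sp$role == "passenger", , drop = FALSE]
    out <- lapply(mat$hairpin_id, function(h) pas$name[pas$hairpin_id == h])
    names(out) <- mat$name
    out
}

#' Reference-length-adjusted isoform sequence
#'
#' Returns the sequence of a length isoform of a species: truncated from
#' the 3' end for lengths below the reference length, or extended with the
#' species' templated 3' hairpin context for longer isoforms.
#'
#' @param dict a \linkS4class{MirnaDictionary}.
#' @param name a species name present in \code{dict}.
#' @param length desired isoform length (nt).
#' @return a character scalar in DNA space.
#' @export
isoformSequence <- function(dict, name, length) {
    sp <- mirnaSpecies(dict)
    i <- match(name, sp$name)
    if (is.na(i)) stop(sprintf("unknown species '%s'", name), call. = FALSE)
    full <- paste0(sp$sequence[i], sp$context3p[i])
    if (length > nchar(full))
        stop(sprintf("isoform length %d exceeds sequence plus 3' context for '%s'",
                     length, name), call. = FALSE)
    substr(full, 1L, length)
}

#' Generate a synthetic miRNA dictionary
#'
#' Emits one mature (guide) and one passenger species per hairpin, with
#' random 22-nt sequences and 10 nt of templated 3' context. A requested
#' fraction of mature species is arranged into shared-13-nt-prefix groups
#' (pairs, plus one triple if the group size is odd) so that prefix
#' collapsing is exercised; all other prefixes are guaranteed distinct.
#'
#' @param nHairpins number of hairpins (>= 1).
#' @param prefixCollisionRate fraction in [0, 1) of mature species that
#'   should sit in shared-prefix groups.
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @param matureLength,passengerLength reference sequence lengths (nt).
#' @return a \linkS4class{MirnaDictionary}.
#' @export
makeMirnaDictionary <- function(nHairpins, prefixCollisionRate = 0,
                                seed = 1L, matureLength = 22L,
                                passengerLength = 22L) {
    .assertScalar(nHairpins, "nHairpins", lower = 1)
    .assertScalar(prefixCollisionRate, "prefixCollisionRate",
                  lower = 0, upper = 1, strictUpper = TRUE)
    nHairpins <- as.integer(nHairpins)
    .withSeed(seed, {
        hp <- sprintf("hp%04d", seq_len(nHairpins))
        matName <- sprintf("syn-mir-%04d-5p", seq_len(nHairpins))
        pasName <- sprintf("syn-mir-%04d-3p", seq_len(nHairpins))

        drawUnique <- function(n, len, avoidPrefixes = character(0)) {
            out <- character(0)
            seen <- avoidPrefixes
            while (length(out) < n) {
                cand <- .randomDna(n - length(out), len)
                pref <- substr(cand, 1L, .PREFIX_LEN)
                keep <- !(pref %in% seen) & !duplicated(pref)
                out <- c(out, cand[keep])
                seen <- c(seen, pref[keep])
            }
            out
        }

        matSeq <- drawUnique(nHairpins, matureLength)
        nShared <- round(prefixCollisionRate * nHairpins)
        if (nShared >= 2L) {
            idx <- sample(nHairpins, nShared)
            # pair members up; an odd count makes the last group a triple
            grp <- rep(seq_len(nShared %/% 2L), each = 2L, length.out = nShared)
            for (g in unique(grp)) {
                ii <- idx[grp == g]
                lead <- substr(matSeq[ii[1L]], 1L, .PREFIX_LEN)
                for (j in ii[-1L])
                    matSeq[j] <- paste0(lead,
                                        substr(matSeq[j], .PREFIX_LEN + 1L,
                                               nchar(matSeq[j])))
            }
        }
        pasSeq <- drawUnique(nHairpins, passengerLength,
                             avoidPrefixes = substr(matSeq, 1L, .PREFIX_LEN))
        ctx <- .randomDna(2L * nHairpins, 10L)

        MirnaDictionary(
            name = c(matName, pasName),
            sequence = c(matSeq, pasSeq),
            hairpinId = c(hp, hp),
            arm = c(rep("5p", nHairpins), rep("3p", nHairpins)),
            role = c(rep("mature", nHairpins), rep("passenger", nHairpins)),
            context3p = ctx)
    })
}

#' Write / read a dictionary as FASTA plus a TSV sidecar
#'
#' The FASTA holds the sequences; the TSV holds name, hairpin_id, arm,
#' role, variant_of and context3p.
#'
#' @param dict a \linkS4class{MirnaDictionary}.
#' @param fasta,tsv file paths.
#' @return \code{writeMirnaDictionary} returns the paths invisibly;
#'   \code{readMirnaDictionary} returns a \linkS4class{MirnaDictionary}.
#' @export
writeMirnaDictionary <- function(dict, fasta, tsv) {
    Biostrings::writeXStringSet(mirnaSequences(dict), fasta)
    utils::write.table(as.data.frame(mirnaSpecies(dict)[, c(
        "name", "hairpin_id", "arm", "role", "variant_of", "context3p")]),
        tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname writeMirnaDictionary
#' @export
readMirnaDictionary <- function(fasta, tsv) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    meta <- utils::read.table(tsv, sep = "\t", header = TRUE,
                              na.strings = "NA",
                              colClasses = "character")
    i <- match(meta$name, names(seqs))
    if (anyNA(i)) stop("TSV names missing from FASTA", call. = FALSE)
    ctx <- meta$context3p
    ctx[is.na(ctx)] <- ""
    MirnaDictionary(name = meta$name,
                    sequence = unname(as.character(seqs)[i]),
                    hairpinId = meta$hairpin_id, arm = meta$arm,
                    role = meta$role, variantOf = meta$variant_of,
                    context3p = ctx)
}
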