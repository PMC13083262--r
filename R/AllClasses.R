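#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats median rnbinom rpois rbinom rlnorm rnorm runif setNames
#'   p.adjust pnorm pt qt var wilcox.test complete.cases
#' @importFrom utils head
NULL

# guide seed occupies nucleotides 2-8; isoform tables span 13-31 nt
.SEED_START <- 2L
.SEED_END <- 8L
.MIN_ISO_LEN <- 13L
.MAX_ISO_LEN <- 31L
.PREFIX_LEN <- 13L

#' MirnaDictionary: a registry of miRNA species
#'
#' Holds mature and passenger miRNA species, their hairpin of origin, and a
#' short stretch of templated 3' hairpin context used when synthesizing
#' length isoforms longer than the reference sequence. Sequences are stored
#' in DNA space (U converted to T) so that read matching is
#' alphabet-agnostic.
#'
#' @slot species a \link[S4Vectors]{DataFrame} with columns \code{name},
#'   \code{sequence}, \code{hairpin_id}, \code{arm} (\code{"5p"} or
#'   \code{"3p"}), \code{role} (\code{"mature"} or \code{"passenger"}),
#'   \code{variant_of} (parent name for processing variants, else
#'   \code{NA}), and \code{context3p} (templated downstream nucleotides,
#'   possibly empty).
#' @export
setClass("MirnaDictionary", slots = c(species = "DFrame"))

setValidity("MirnaDictionary", function(object) {
    sp <- object@species
    need <- c("name", "sequence", "hairpin_id", "arm", "role",
              "variant_of", "context3p")
    if (!all(need %in% colnames(sp)))
        return(paste("species must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(sp$name))
        return("species names must be unique")
    if (nrow(sp) && any(nchar(sp$sequence) < .PREFIX_LEN))
        return("all sequences must be at least 13 nt")
    if (nrow(sp) && !all(sp$arm %in% c("5p", "3p")))
        return("arm must be '5p' or '3p'")
    if (nrow(sp) && !all(sp$role %in% c("mature", "passenger")))
        return("role must be 'mature' or 'passenger'")
    if (nrow(sp) && any(grepl("[^ACGT]", sp$sequence)))
        return("sequences must be A/C/G/T (U is converted on construction)")
    TRUE
})

#' CollapsedIndex: 13-nt prefix lookup with collapsing
#'
#' Maps each distinct 13-nt sequence prefix to a single collapsed entry;
#' species sharing a prefix are indistinguishable by prefix matching and
#' are merged, with the collapsed name joining all member names.
#'
#' @slot prefixes character vector of distinct 13-nt prefixes (DNA space).
#' @slot collapsedNames character vector, parallel to \code{prefixes}.
#' @slot members list of character vectors of member species names.
#' @export
setClass("CollapsedIndex",
    slots = c(prefixes = "character", collapsedNames = "character",
              members = "list"))

setValidity("CollapsedIndex", function(object) {
    if (length(object@prefixes) != length(object@collapsedNames) ||
        length(object@prefixes) != length(object@members))
        return("prefixes, collapsedNames and members must be parallel")
    if (anyDuplicated(object@prefixes))
        return("prefixes must be unique")
    if (length(object@prefixes) && any(nchar(object@prefixes) != .PREFIX_LEN))
        return("all prefixes must be 13 nt")
    if (length(object@members) && any(lengths(object@members) < 1L))
        return("every entry needs at least one member")
    TRUE
})

#' IsoformCountTable: counts by (collapsed miRNA, length, sample)
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose rows are
#' (collapsed miRNA, isoform length) pairs with lengths in 13-31 nt and
#' whose columns are sequencing libraries. Per-sample read-provenance
#' counters (total, adapter-rejected, quality-rejected, too-short,
#' too-long, unassigned, assigned) live in \code{colData}; simulation
#' ground truth, when present, lives in \code{metadata()$truth}.
#'
#' @export
setClass("IsoformCountTable", contains = "SummarizedExperiment")

setValidity("IsoformCountTable", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("mirna", "length") %in% colnames(rd)))
        return("rowData must have 'mirna' and 'length'")
    len <- rd$length
    if (length(len) && (any(len < .MIN_ISO_LEN) || any(len > .MAX_ISO_LEN)))
        return("isoform lengths must lie in [13, 31]")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
        return("counts must be nonnegative integers")
    cd <- SummarizedExperiment::colData(object)
    counters <- c("adapter_rejected", "quality_rejected", "too_short",
                  "too_long", "unassigned", "assigned")
    if (all(c("total_reads", counters) %in% colnames(cd))) {
        if (!isTRUE(all.equal(unname(cd$assigned), unname(colSums(cts)))))
            return("'assigned' counter must equal the column sums")
        tot <- rowSums(as.matrix(cd[, counters]))
        if (!isTRUE(all.equal(unname(tot), unname(cd$total_reads))))
            return("provenance counters must sum to total_reads")
    }
    TRUE
})

#' SimulationTruth: ground truth for isoform-count simulation
#'
#' Defines a two-group (knockout vs control) small-RNA experiment: expected
#' abundance of each species at its reference length, its distribution over
#' isoform lengths 13-31 nt, a per-species true log2 knockout/control
#' effect applied to all isoforms (TDMD-style destabilization acts on every
#' length), an additional length-dependent log2 effect applied only to
#' isoforms shorter than \code{shortThreshold} (default 19 nt), per-species
#' negative-binomial dispersions, and true per-sample size factors.
#'
#' @export
setClass("SimulationTruth",
    slots = c(design = "character", baseAbundance = "numeric",
              lengthProfile = "matrix", lfcTdmd = "numeric",
              lfcShort = "numeric", dispersion = "numeric",
              sizeFactorTruth = "numeric", shortThreshold = "integer",
              seed = "integer"))

setValidity("SimulationTruth", function(object) {
    if (!all(object@design %in% c("KO", "control")))
        return("design groups must be 'KO' or 'control'")
    if (is.null(names(object@design)) || anyDuplicated(names(object@design)))
        return("design must be named by unique sample names")
    if (any(object@dispersion < 0)) return("dispersions must be >= 0")
    if (any(object@sizeFactorTruth <= 0)) return("size factors must be > 0")
    prof <- object@lengthProfile
    if (ncol(prof) != (.MAX_ISO_LEN - .MIN_ISO_LEN + 1L))
        return("lengthProfile must have one column per length 13..31")
    if (nrow(prof) && any(abs(rowSums(prof) - 1) > 1e-8))
        return("lengthProfile rows must sum to 1")
    if (any(prof < 0)) return("lengthProfile must be nonnegative")
    ok <- all(vapply(list(object@baseAbundance, object@lfcTdmd,
                          object@lfcShort, object@dispersion),
                     function(x) identical(names(x), rownames(prof)),
                     logical(1)))
    if (!ok) return("per-species vectors must be named like lengthProfile rows")
    TRUE
})

#' GelTruth: ground truth for a simulated co-IP gel
#'
#' Describes the lanes of a co-immunoprecipitation experiment: for each
#' lane a bait (\code{"ZSWIM8"} at some concentration, the pan-AGO
#' \code{"T6B"} peptide control, or \code{"none"} for the 0 nM background
#' lane), a target label, and the true fraction of radiolabelled target
#' recovered. Band intensity is modelled as
#' \code{background + gain * fraction * (1 + noise)} with log-normal
#' multiplicative noise of coefficient of variation \code{noiseCv}.
#'
#' @export
setClass("GelTruth",
    slots = c(lanes = "DFrame", trueFractionBound = "numeric",
              backgroundLevel = "numeric", gain = "numeric",
              noiseCv = "numeric", seed = "integer"))

setValidity("GelTruth", function(object) {
    ln <- object@lanes
    need <- c("target_label", "bait_label", "bait_conc")
    if (!all(need %in% colnames(ln)))
        return(paste("lanes must have columns:", paste(need, collapse = ", ")))
    if (nrow(ln) != length(object@trueFractionBound))
        return("one true fraction per lane required")
    f <- object@trueFractionBound
    if (any(f < 0 | f > 1)) return("fractions must lie in [0, 1]")
    for (tg in unique(ln$target_label)) {
        sub <- ln[ln$target_label == tg, ]
        if (sum(sub$bait_label == "T6B") != 1L)
            return(sprintf("target '%s' needs exactly one T6B lane", tg))
        if (sum(sub$bait_label == "none") != 1L)
            return(sprintf("target '%s' needs exactly one 0 nM (no-bait) lane", tg))
    }
    if (object@noiseCv < 0) return("noiseCv must be >= 0")
    if (object@backgroundLevel < 0) return("backgroundLevel must be >= 0")
    if (object@gain <= 0) return("gain must be > 0")
    TRUE
})

#' GelQuant: quantified gel-band intensities
#'
#' Raw per-lane band intensities plus blank-rectangle intensities used for
#' image-background estimation. Produced by \code{\link{simulateCoipGel}}
#' or assembled from an external lane table; consumed by
#' \code{\link{quantifyGel}}.
#'
#' @export
setClass("GelQuant",
    slots = c(lanes = "DFrame", blanks = "numeric", truth = "list"))

setValidity("GelQuant", function(object) {
    need <- c("target_label", "bait_label", "bait_conc", "intensity")
    if (!all(need %in% colnames(object@lanes)))
        return(paste("lanes must have columns:", paste(need, collapse = ", ")))
    if (!length(object@blanks))
        return("at least one blank-rectangle intensity is required")
    TRUE
})

#' TitrationCurve: a filter-binding dilution series
#'
#' Stores the dilution factors and observed fractions bound of a titration
#' of AGO-miRNA complex (RISC) against a fixed total target concentration,
#' along with fit results of the quadratic (ligand-depletion) binding
#' isotherm: the RISC stock concentration, the dissociation constant
#' \eqn{K_D} and the plateau \eqn{F_{max}}.
#'
#' @slot dilutionFactors unitless dilution factors (DF), one per point.
#' @slot fractionBound observed fraction of target bound, in [0, 1].
#' @slot targetTotal total target concentration (nM).
#' @slot fitted named list with \code{stock}, \code{kd}, \code{fmax}
#'   (empty before fitting).
#' @slot diagnostics list with residual norm, convergence flag and the
#'   start grid used.
#' @slot truth simulation ground truth, if generated.
#' @export
setClass("TitrationCurve",
    slots = c(dilutionFactors = "numeric", fractionBound = "numeric",
              targetTotal = "numeric", fitted = "list",
              diagnostics = "list", truth = "list"))

setValidity("TitrationCurve", function(object) {
    if (length(object@dilutionFactors) != length(object@fractionBound))
        return("dilutionFactors and fractionBound must be parallel")
    if (any(object@dilutionFactors <= 0))
        return("dilution factors must be > 0")
    d <- diff(object@dilutionFactors)
    if (length(d) && !(all(d > 0) || all(d < 0)))
        return("dilution factors must be strictly monotone")
    if (length(object@targetTotal) != 1L || object@targetTotal <= 0)
        return("targetTotal must be a single positive concentration")
    if (any(object@fractionBound < -0.5 | object@fractionBound > 1.5))
        return("fractionBound grossly outside [0, 1]")
    TRUE
})

#' StabilityResult: per-miRNA differential stability results
#'
#' One row per collapsed miRNA: summed log2 knockout/control fold change,
#' its standard error, Wald p-value, BH-adjusted p-value, the three
#' potential-sensitivity flags (adjusted-p + positive fold change;
#' mature/passenger separation beyond joint standard errors; external
#' annotation), and the resulting exclusion call.
#'
#' @export
setClass("StabilityResult",
    slots = c(table = "DFrame", design = "character"))

setValidity("StabilityResult", function(object) {
    tab <- object@table
    if (!all(c("mirna", "lfc", "se", "p") %in% colnames(tab)))
        return("table must have at least mirna, lfc, se, p")
    if ("padj" %in% colnames(tab)) {
        ok <- complete.cases(tab$p, tab$padj)
        if (any(tab$padj[ok] < tab$p[ok] - 1e-12))
            return("padj must be >= p")
    }
    TRUE
})

#' IsoformFoldChanges: per-(miRNA, length) fold changes
#'
#' Log2 knockout/control fold changes of individual length isoforms
#' computed on counts normalized with size factors derived from the
#' summed (per-miRNA) counts, optionally centered by subtracting the
#' median fold change of all 22-nt species.
#'
#' @export
setClass("IsoformFoldChanges",
    slots = c(table = "DFrame", centered = "logical", median22 = "numeric"))

setValidity("IsoformFoldChanges", function(object) {
    tab <- object@table
    if (!all(c("mirna", "length", "lfc") %in% colnames(tab)))
        return("table must have mirna, length, lfc")
    if (isTRUE(object@centered) && !"centered_lfc" %in% colnames(tab))
        return("centered objects must carry centered_lfc")
    TRUE
})

#' DuplexAnnotation: architecture of a miRNA-target duplex
#'
#' Describes how a target RNA pairs to a miRNA guide: the seed block
#' (guide nucleotides 2-8), the best 3'-region block (guide nucleotides
#' >= 9), the internal loop on each strand separating the two blocks, the
#' target flank lengths outside the outermost paired nucleotides, and the
#' resulting architecture class (\code{seed_only}, \code{supplementary},
#' \code{tdmd_like}, \code{full} or \code{no_site}). Guide nucleotide 1 is
#' never paired (anchored in AGO). Coordinates are 1-based inclusive,
#' guide and target both 5' to 3'.
#'
#' @export
setClass("DuplexAnnotation",
    slots = c(guide = "character", target = "character",
              seedSite = "integer", seedSpan = "integer",
              threePrimeSpan = "integer", loopGuide = "integer",
              loopTarget = "integer", flank5 = "integer",
              flank3 = "integer", totalPaired = "integer",
              targetPairedRange = "integer", architecture = "character"))

setValidity("DuplexAnnotation", function(object) {
    if (object@architecture == "no_site") return(TRUE)
    if (length(intersect(object@seedSpan, object@threePrimeSpan)))
        return("seed and 3' spans must not overlap")
    if (object@totalPaired !=
        length(object@seedSpan) + length(object@threePrimeSpan))
        return("totalPaired must equal |seedSpan| + |threePrimeSpan|")
    if (object@loopGuide < 0 || object@loopTarget < 0)
        return("loop lengths must be >= 0")
    if (object@flank5 < 0 || object@flank3 < 0)
        return("flank lengths must be >= 0")
    if (object@architecture == "full" &&
        (object@loopGuide != 0L || object@loopTarget != 0L))
        return("full duplexes must have zero-length loops")
    TRUE
})
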