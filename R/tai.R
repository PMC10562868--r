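.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Default wobble-pairing penalties for tAI weights
#'
#' One selective constraint s per codon-anticodon pairing class at the third
#' codon position, Watson-Crick pairings at 0. Class names are
#' "<anticodon wobble base>:<codon third base>" in RNA letters, with I the
#' inosine arising from genomic A at the anticodon wobble position. The
#' defaults are the canonical constraint values of the tAI literature; all
#' are configurable.
#'
#' @return named numeric vector of penalties in [0, 1].
#' @export
defaultWobbleS <- function() {
    c("I:U" = 0, "G:U" = 0.41,
      "G:C" = 0, "I:C" = 0.28,
      "U:A" = 0, "I:A" = 0.9999,
      "C:G" = 0, "U:G" = 0.68)
}

.revcompDNA <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' tRNA adaptation index weights from tRNA gene copy numbers
#'
#' For each sense codon the absolute adaptiveness is
#' W_c = sum over pairings of (1 - s) * tGCN(anticodon), the sum running
#' over the Watson-Crick anticodon and the one wobble anticodon of the
#' codon's third base (U: I/G wobble, C: G/I, A: U/I, G: C/U; I encoded as
#' genomic A). Relative weights are w_c = W_c / max(W); codons with W = 0
#' receive the geometric mean of the nonzero weights. Stop codons are
#' excluded.
#'
#' @param tGCN named non-negative integer vector, anticodon (DNA letters,
#'   5'->3') -> tRNA gene copy number. Anticodons absent from the vector
#'   count 0 copies.
#' @param sTable named penalties per pairing class (see
#'   \code{\link{defaultWobbleS}}); missing classes default to their
#'   canonical values.
#' @return A \linkS4class{TAIModel}.
#' @examples
#' # one two-codon box: GGT read by ACC tRNA (2 copies) perfectly and by
#' # nothing else; GGC has no perfect match but G:C? -- see tests for the
#' # worked two-codon example.
#' m <- taiWeights(c(AAA = 2), defaultWobbleS())
#' @export
taiWeights <- function(tGCN, sTable = defaultWobbleS()) {
    if (any(tGCN < 0)) stop("tRNA gene copy numbers must be non-negative")
    s <- defaultWobbleS()
    s[names(sTable)] <- sTable
    if (any(s < 0) || any(s > 1)) stop("penalties must lie in [0, 1]")
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    codons <- setdiff(codons, .STOP_CODONS)
    # pairing table: codon third base -> (wobble anticodon base, class)
    pairings <- list(
        "T" = list(c("A", "I:U"), c("G", "G:U")),
        "C" = list(c("G", "G:C"), c("A", "I:C")),
        "A" = list(c("T", "U:A"), c("A", "I:A")),
        "G" = list(c("C", "C:G"), c("T", "U:G")))
    gcn <- function(ac) if (ac %in% names(tGCN)) tGCN[[ac]] else 0
    W <- setNames(numeric(length(codons)), codons)
    for (cod in codons) {
        third <- substr(cod, 3, 3)
        acWC <- .revcompDNA(cod)   # perfect anticodon
        for (pp in pairings[[third]]) {
            ac <- acWC
            substr(ac, 1, 1) <- pp[1]
            W[cod] <- W[cod] + (1 - s[[pp[2]]]) * gcn(ac)
        }
    }
    w <- W / max(W)
    if (all(W == 0)) stop("no codon has a pairing; check tGCN")
    nz <- w > 0
    wGeo <- exp(mean(log(w[nz])))
    w[!nz] <- wGeo
    methods::new("TAIModel", tGCN = tGCN, s = s, W = W, w = w, wGeo = wGeo)
}

.splitCodons <- function(seqChar) {
    L <- nchar(seqChar)
    substring(seqChar, seq(1, L - 2, 3), seq(3, L, 3))
}

#' Gene tRNA adaptation index (classical translational efficiency)
#'
#' The geometric mean of the relative codon weights over a CDS, excluding
#' the start codon and the stop codon:
#' tai = exp(mean over codons 2..L-1 of ln w). This per-gene score is the
#' codon-optimality measure reported as classical TE, codon usage entering
#' through the gene's own codon composition.
#'
#' @param cds a CDS sequence (character or \code{DNAString}); must start
#'   with ATG, end with a stop codon and have length a multiple of 3 with
#'   at least one internal codon.
#' @param model a \linkS4class{TAIModel}.
#' @return numeric scalar in (0, 1].
#' @export
geneTai <- function(cds, model) {
    s <- toupper(as.character(cds))
    L <- nchar(s)
    if (L %% 3 != 0 || L < 9)
        stop("CDS length must be a multiple of 3 and >= 9 nt")
    cods <- .splitCodons(s)
    if (cods[1] != "ATG") stop("CDS must start with ATG")
    if (!cods[length(cods)] %in% .STOP_CODONS)
        stop("CDS must end with a stop codon")
    internal <- cods[2:(length(cods) - 1)]
    isStop <- internal %in% .STOP_CODONS
    if (any(isStop))
        stop("internal stop codon at codon position ", which(isStop)[1] + 1)
    exp(mean(log(model@w[internal])))
}

#' Gene tAI over a set of CDS sequences
#'
#' @param annotation a \linkS4class{TranscriptAnnotation} or a named
#'   \code{DNAStringSet} of CDSs.
#' @param model a \linkS4class{TAIModel}.
#' @return data.frame with columns gene, tai and classicalTe (identical by
#'   construction; the column is kept so downstream property tables can
#'   consume the score under its reported name).
#' @export
genesTai <- function(annotation, model) {
    cds <- if (methods::is(annotation, "TranscriptAnnotation"))
        annotation@cds else annotation
    tai <- vapply(as.character(cds), geneTai, 0, model = model,
                  USE.NAMES = FALSE)
    data.frame(gene = names(cds), tai = tai, classicalTe = tai,
               row.names = NULL)
}

#' A synthetic tRNA gene copy number table
#'
#' Copy numbers for a toy genome in which every sense codon's Watson-Crick
#' anticodon is present, with copies drawn to span the realistic range
#' (1-11) so that codon weights vary. Labelled synthetic: it stands in for
#' an organism's genomic tRNA census in simulations and tests.
#'
#' @param seed integer seed.
#' @return named integer vector, anticodon -> copies.
#' @export
syntheticTGCN <- function(seed = 1) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    codons <- setdiff(codons, .STOP_CODONS)
    acs <- vapply(codons, .revcompDNA, "")
    setNames(sample(1:11, length(acs), replace = TRUE), acs)
}
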