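## Sequence -> atomic inventory with exchangeable/non-exchangeable hydrogen
## classes, and sequence-based molecular weight.

#' Parse an RNA sequence into residue counts
#'
#' Accepts a raw sequence string or single-record FASTA text (header lines
#' beginning with \code{>} are stripped).  Whitespace is ignored, lowercase
#' is accepted, and \code{T} is silently mapped to \code{U} with a warning
#' (tolerant FASTA ingestion of DNA-alphabet files).
#'
#' @param text character; sequence or FASTA text (possibly multi-line).
#' @return named integer vector of residue counts over \code{A, C, G, U};
#'   its sum is the chain length.
#' @examples
#' parseSequence("GCGC")
#' parseSequence(">loop\ngcgcgc")
#' @export
parseSequence <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- lines[!grepl("^>", lines)]
  seq <- toupper(gsub("[[:space:]]", "", paste(lines, collapse = "")))
  if (!nzchar(seq))
    stop("empty sequence after stripping headers and whitespace")
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U", "T"))
  if (length(bad))
    stop(sprintf("unknown character '%s' at position %d", chars[bad[1]],
                 bad[1]))
  if (any(chars == "T")) {
    warning("sequence contains T; mapped to U")
    chars[chars == "T"] <- "U"
  }
  counts <- vapply(c("A", "C", "G", "U"), function(b) sum(chars == b),
                   integer(1))
  counts
}

#' Read a FASTA file of RNA sequences
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning plain
#' character sequences named by record.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

.checkTermini <- function(fivePrime, threePrime) {
  fivePrime <- match.arg(fivePrime, c("hydroxyl", "monophosphate",
                                      "triphosphate"))
  threePrime <- match.arg(threePrime, c("hydroxyl", "phosphate"))
  c(fivePrime, threePrime)
}

#' Atomic inventory of an RNA chain
#'
#' Builds element totals for a linear RNA from residue counts and terminal
#' chemistry, splitting hydrogens into the non-exchangeable (carbon-bonded)
#' and exchangeable (N/O-bonded) classes.  The chain formula is assembled as
#' the sum of free nucleoside-5'-monophosphate formulas minus (n-1) waters;
#' phosphate groups are then taken as ionized (no acidic protons, the state
#' at neutral pH), and the termini adjusted: a 5'-hydroxyl removes HPO3 and
#' adds the terminal hydroxyl proton, a 5'-triphosphate adds two HPO3 units,
#' and a 3'-phosphate adds one.  Every residue keeps its 2'-OH proton in the
#' exchangeable class.
#'
#' @param x a sequence string (passed to [parseSequence()]) or a named
#'   residue-count vector as returned by it.
#' @param fivePrime one of \code{"hydroxyl"} (default), \code{"monophosphate"},
#'   \code{"triphosphate"}.
#' @param threePrime one of \code{"hydroxyl"} (default), \code{"phosphate"}.
#' @return an [AtomInventory-class].
#' @examples
#' atomInventory("UU")
#' atomInventory("GCGCGC", fivePrime = "triphosphate")
#' @export
atomInventory <- function(x, fivePrime = "hydroxyl",
                          threePrime = "hydroxyl") {
  rc <- if (is.character(x)) parseSequence(x) else x
  stopifnot(is.numeric(rc), all(c("A", "C", "G", "U") %in% names(rc)),
            all(rc >= 0))
  n <- sum(rc)
  if (n < 1) stop("empty residue counts")
  term <- .checkTermini(fivePrime, threePrime)

  tot <- c(C = 0, N = 0, O = 0, P = 0, Hn = 0, He = 0)
  for (b in c("A", "C", "G", "U")) tot <- tot + rc[[b]] * .NMP[[b]]

  ## condense: -(n-1) H2O (each removes 2 exchangeable H and 1 O)
  tot[["He"]] <- tot[["He"]] - 2 * (n - 1)
  tot[["O"]] <- tot[["O"]] - (n - 1)
  ## ionized phosphates: free-acid NMPs carry 2 P-OH each; after
  ## condensation the chain retains (n-1) diester OH + 2 on the 5' terminus;
  ## drop them all, then restore non-phosphate terminal protons below.
  tot[["He"]] <- tot[["He"]] - (n - 1) - 2

  if (term[1] == "hydroxyl") {
    tot[["P"]] <- tot[["P"]] - 1
    tot[["O"]] <- tot[["O"]] - 3
    tot[["He"]] <- tot[["He"]] + 1        # 5'-OH proton
  } else if (term[1] == "triphosphate") {
    tot[["P"]] <- tot[["P"]] + 2
    tot[["O"]] <- tot[["O"]] + 6
  }
  if (term[2] == "phosphate") {
    tot[["P"]] <- tot[["P"]] + 1
    tot[["O"]] <- tot[["O"]] + 3
    tot[["He"]] <- tot[["He"]] - 1        # 3'-OH esterified
  }

  counts <- c(C = tot[["C"]], N = tot[["N"]], O = tot[["O"]], P = tot[["P"]])
  inv <- new("AtomInventory", counts = counts, hNonexch = tot[["Hn"]],
             hExch = tot[["He"]], massProtiated = 0,
             residueCounts = c(A = rc[["A"]], C = rc[["C"]], G = rc[["G"]],
                               U = rc[["U"]]),
             termini = term)
  inv@massProtiated <- molecularWeight(inv, d = 0)
  validObject(inv)
  inv
}

#' Sequence-based molecular weight
#'
#' Molecular weight of the chain in kDa at non-exchangeable deuteration
#' fraction \code{d}.  Non-exchangeable hydrogen mass is
#' \code{(1-d) m_H + d m_D}; exchangeable hydrogens are counted as 1H, so
#' \code{d = 0} gives the protiated mass.
#'
#' @param inv an [AtomInventory-class].
#' @param d deuteration fraction of non-exchangeable hydrogens, in \[0, 1\].
#' @return mass in kDa.
#' @examples
#' molecularWeight(atomInventory("GGGCGGUGGUGC"))
#' @export
molecularWeight <- function(inv, d = 0) {
  stopifnot(is(inv, "AtomInventory"))
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0 || d > 1)
    stop("d must be a single number in [0, 1]")
  heavy <- sum(inv@counts * .AMASS[c("C", "N", "O", "P")])
  h <- inv@hNonexch * ((1 - d) * .AMASS[["H"]] + d * .AMASS[["D"]]) +
    inv@hExch * .AMASS[["H"]]
  unname(heavy + h) / 1000
}
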