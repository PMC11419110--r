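## Readers/writers: three-column .dat scattering profiles and PDB
## coordinate files, plus the ScatteringProfile / AtomicModel constructors.

#' Construct a ScatteringProfile
#'
#' @param q scattering vector, 1/A (sorted internally if needed, with a
#'   warning).
#' @param intensity intensities, same length as q.
#' @param sigma optional uncertainties (positive), same length as q.
#' @param metadata free-form list of provenance key/values.
#' @param qUnits \code{"A"} (default) or \code{"nm"}; nm^-1 input is divided
#'   by 10 on construction.
#' @return a [ScatteringProfile-class].
#' @examples
#' ScatteringProfile(q = seq(0.01, 0.3, 0.01),
#'                   intensity = exp(-seq(0.01, 0.3, 0.01)^2 * 75))
#' @export
ScatteringProfile <- function(q, intensity, sigma = numeric(0),
                              metadata = list(), qUnits = c("A", "nm")) {
  qUnits <- match.arg(qUnits)
  if (qUnits == "nm") q <- q / 10
  if (is.unsorted(q, strictly = TRUE)) {
    warning("q not strictly increasing; sorting")
    o <- order(q)
    q <- q[o]; intensity <- intensity[o]
    if (length(sigma)) sigma <- sigma[o]
    keep <- !duplicated(q)
    q <- q[keep]; intensity <- intensity[keep]
    if (length(sigma)) sigma <- sigma[keep]
  }
  obj <- new("ScatteringProfile", q = as.numeric(q),
             intensity = as.numeric(intensity), sigma = as.numeric(sigma),
             metadata = metadata)
  validObject(obj)
  obj
}

#' Read a reduced scattering profile (.dat)
#'
#' Parses whitespace-delimited 2/3/4-column numeric rows (q, I\[, sigma\]).
#' Lines prefixed with \code{#} and non-numeric header/footer text are
#' skipped and preserved in the profile metadata.  A fourth column, when
#' present, is ignored beyond the first three.
#'
#' @param path file to read.
#' @param qUnits \code{"A"} or \code{"nm"} (nm^-1 is converted on read).
#' @return a [ScatteringProfile-class]; \code{sigma} is empty for 2-column
#'   files (downstream weighted fits will then refuse to run).
#' @export
readDat <- function(path, qUnits = c("A", "nm")) {
  qUnits <- match.arg(qUnits)
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  isNum <- vapply(fields, function(f) {
    length(f) >= 2 && !grepl("^#", f[1]) &&
      !anyNA(suppressWarnings(as.numeric(f[seq_len(min(3, length(f)))])))
  }, logical(1))
  if (sum(isNum) < 3)
    stop("fewer than 3 numeric data rows in ", path)
  header <- lines[!isNum & nzchar(trimws(lines))]
  rows <- fields[isNum]
  ncols <- min(vapply(rows, length, integer(1)))
  mat <- t(vapply(rows, function(f)
    suppressWarnings(as.numeric(f[seq_len(min(3, ncols))])),
    numeric(min(3, ncols))))
  sigma <- if (ncol(mat) >= 3) mat[, 3] else numeric(0)
  if (length(sigma) && any(!is.finite(sigma) | sigma <= 0)) {
    keep <- is.finite(sigma) & sigma > 0
    mat <- mat[keep, , drop = FALSE]
    sigma <- sigma[keep]
  }
  ScatteringProfile(q = mat[, 1], intensity = mat[, 2], sigma = sigma,
                    metadata = list(source = path, header = header),
                    qUnits = qUnits)
}

#' Write a scattering profile as three-column .dat
#'
#' Writes \code{q I sigma} (sigma column omitted when absent) with a
#' \code{#} provenance header; values use full double precision so that
#' \code{readDat(writeDat(p))} round-trips to 1e-10.
#'
#' @param profile a [ScatteringProfile-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDat <- function(profile, path) {
  stopifnot(is(profile, "ScatteringProfile"))
  md <- profile@metadata
  hdr <- c(sprintf("# nucsolv scattering profile (%d points)",
                   length(profile@q)),
           if (length(md))
             sprintf("# %s: %s", names(md),
                     vapply(md, function(v) paste(format(v), collapse = " "),
                            character(1))),
           if (length(profile@sigma)) "# q I sigma" else "# q I")
  cols <- if (length(profile@sigma))
    cbind(profile@q, profile@intensity, profile@sigma)
  else cbind(profile@q, profile@intensity)
  body <- apply(cols, 1, function(r)
    paste(formatC(r, format = "e", digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## PDB input

#' Construct an AtomicModel
#'
#' @param particles data.frame with columns \code{element, x, y, z, resid,
#'   resno, chain, hNonexch, hExch, volume} (hydrogen counts are implicit
#'   riding hydrogens; volume is the displaced solvent volume in A^3).
#' @param chainD named numeric; per-chain non-exchangeable deuteration
#'   fraction, covering every chain in \code{particles}.
#' @return an [AtomicModel-class].
#' @export
atomicModel <- function(particles, chainD) {
  obj <- new("AtomicModel", particles = particles, chainD = chainD)
  validObject(obj)
  obj
}

.elementFromName <- function(elety) {
  ## atom-name heuristic: first alphabetic character that names an element
  ## we know; handles "C1'", "OP1", "N3", "P"
  first <- substr(gsub("[^A-Za-z].*$", "", toupper(elety)), 1, 1)
  ifelse(first %in% names(.BCOH), first, NA_character_)
}

#' Read an atomic model from a PDB file
#'
#' Reads heavy atoms of RNA residues via [bio3d::read.pdb()]; hydrogens are
#' implicit: each heavy atom carries its riding hydrogen count
#' (exchangeable/non-exchangeable from the residue templates), so
#' unprotonated PDB files are handled.  Waters are skipped.  The element is
#' taken from the element column when present, otherwise from an atom-name
#' heuristic.  Terminal 5'-OH and 3'-OH protons are added to the first/last
#' residue of each chain (the 5' proton only when the first residue carries
#' no phosphate).
#'
#' @param path PDB file.
#' @param chain optional chain filter (character vector of chain ids).
#' @param chainD named per-chain deuteration fractions; defaults to 0
#'   (protiated) for every chain.
#' @return an [AtomicModel-class].
#' @export
readPDB <- function(path, chain = NULL, chainD = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop("no atoms after filtering")
  ## drop explicit hydrogens; riding hydrogens are added from templates
  elem <- toupper(trimws(at$elesy))
  elem[!nzchar(elem) | is.na(elem)] <- NA
  elem[is.na(elem)] <- .elementFromName(at$elety[is.na(elem)])
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  elem <- elem[!(elem %in% c("H", "D"))]
  if (anyNA(elem))
    stop("unknown element for atom(s): ",
         paste(unique(at$elety[is.na(elem)]), collapse = ", "))
  resmap <- c(A = "A", G = "G", C = "C", U = "U", RA = "A", RG = "G",
              RC = "C", RU = "U", ADE = "A", GUA = "G", CYT = "C",
              URA = "U", URI = "U")
  res <- resmap[toupper(trimws(at$resid))]
  if (anyNA(res))
    stop("unknown residue(s): ",
         paste(unique(at$resid[is.na(res)]), collapse = ", "))

  name <- toupper(trimws(at$elety))
  name <- gsub("\\*", "'", name)  # old-style primes
  hN <- hE <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    tpl <- .RIDING_H_BACKBONE[[name[i]]]
    if (is.null(tpl)) tpl <- .RIDING_H_BASE[[res[i]]][[name[i]]]
    if (is.null(tpl)) tpl <- c(0, 0)  # unrecognised heavy atom: no riding H
    hN[i] <- tpl[1]; hE[i] <- tpl[2]
  }
  ## terminal hydroxyl protons per chain
  for (ch in unique(at$chain)) {
    idx <- which(at$chain == ch)
    resnos <- at$resno[idx]
    firstRes <- idx[resnos == min(resnos)]
    lastRes <- idx[resnos == max(resnos)]
    if (!any(name[firstRes] == "P")) {
      o5 <- firstRes[name[firstRes] == "O5'"]
      if (length(o5)) hE[o5[1]] <- hE[o5[1]] + 1
    }
    o3 <- lastRes[name[lastRes] == "O3'"]
    if (length(o3)) hE[o3[1]] <- hE[o3[1]] + 1
  }
  vol <- .VDISP[elem] + (hN + hE) * .VDISP[["H"]]
  particles <- data.frame(element = elem, x = at$x, y = at$y, z = at$z,
                          resid = res, resno = at$resno, chain = at$chain,
                          hNonexch = hN, hExch = hE, volume = unname(vol),
                          stringsAsFactors = FALSE)
  chains <- unique(particles$chain)
  if (is.null(chainD)) chainD <- setNames(rep(0, length(chains)), chains)
  if (!all(chains %in% names(chainD)))
    stop("missing chain label(s) for: ",
         paste(setdiff(chains, names(chainD)), collapse = ", "))
  atomicModel(particles, chainD[chains])
}

#' Write a bead or atomic model as PDB
#'
#' Minimal PDB output (ATOM records, chain and residue numbering preserved)
#' via [bio3d::write.pdb()]; bead particles are written as carbon atoms of
#' residue \code{BEA}.
#'
#' @param model an [AtomicModel-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(model, path) {
  p <- model@particles
  isBead <- p$element == "BEAD"
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(p[, c("x", "y", "z")]))),
                   resno = p$resno, chain = p$chain,
                   resid = ifelse(isBead, "BEA", p$resid),
                   elety = ifelse(isBead, "C", p$element))
  invisible(path)
}
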