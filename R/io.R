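#' Read a molecule from SMILES or SDF
#'
#' Parses a molecule into a \linkS4class{MolecularGraph}. Hydrogens are made
#' explicit if absent (parametrization is always based on an all-atom
#' representation). Atom ids are 0-based and follow the SDF atom-block
#' order, which is deterministic for a given input.
#'
#' @param source SMILES string, SDF record text, or path to an SDF file.
#' @param format "smiles" or "sdf".
#' @param name molecule name; defaults to the SDF title or the SMILES
#'   string.
#' @param addHydrogens logical; add explicit hydrogens where the input has
#'   implicit ones (default TRUE). Set FALSE to read intentionally
#'   unsaturated graphs verbatim from SDF.
#' @return a validated \linkS4class{MolecularGraph}.
#' @examples
#' ph <- readMolecule("Oc1ccccc1", format = "smiles", name = "phenol")
#' numAtoms(ph)  # 13
#' @export
readMolecule <- function(source, format = c("smiles", "sdf"), name = NULL,
                         addHydrogens = TRUE) {
  format <- match.arg(format)
  if (!is.character(source) || length(source) != 1 || !nzchar(trimws(source)))
    stop("parse error: empty ", format, " input", call. = FALSE)
  if (format == "smiles") {
    sdfText <- tryCatch({
      if (addHydrogens)
        ChemmineOB::convertFormat("SMI", "SDF", source,
                                  options = data.frame(names = "h",
                                                       args = ""))
      else ChemmineOB::convertFormat("SMI", "SDF", source)
    }, error = function(e) stop("parse error in SMILES '", source, "': ",
                                conditionMessage(e), call. = FALSE))
    if (!nzchar(trimws(sdfText)) || !grepl("V2000", sdfText))
      stop("parse error: SMILES '", source, "' could not be interpreted",
           call. = FALSE)
    if (is.null(name)) name <- source
  } else {
    sdfText <- if (file.exists(source)) {
      paste(readLines(source, warn = FALSE), collapse = "\n")
    } else source
    if (!grepl("V2000", sdfText))
      stop("parse error: no V2000 counts line found in SDF input",
           call. = FALSE)
    if (addHydrogens) {
      sdfText <- tryCatch(
        ChemmineOB::convertFormat("SDF", "SDF", sdfText,
                                  options = data.frame(names = "h",
                                                       args = "")),
        error = function(e) stop("parse error in SDF input: ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  g <- .parseSDFText(sdfText, name = name)
  validObject(g)
  g
}

# Parse the first record of SDF V2000 text into a MolecularGraph.
# ChemmineR does the atom/bond block parsing; formal charges are taken from
# "M  CHG" lines (which ChemmineR does not expose) and partial charges from
# a PARTIAL_CHARGES data field (one value per atom line, e units).
.parseSDFText <- function(sdfText, name = NULL) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  txt <- sub("\n*$", "\n", sdfText)
  if (!grepl("\\$\\$\\$\\$", txt)) txt <- paste0(txt, "$$$$\n")
  writeLines(txt, tf, sep = "")
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                     error = function(e)
                       stop("parse error in SDF record: ",
                            conditionMessage(e), call. = FALSE))
  if (length(sdfset) < 1)
    stop("parse error: SDF input contains no molecule record",
         call. = FALSE)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (!is.matrix(ab) || nrow(ab) == 0)
    stop("parse error: empty atom block", call. = FALSE)
  elements <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  atomsDf <- data.frame(
    id = seq_len(n) - 1L,
    element = elements,
    formal_charge = 0L,
    partial_charge = NA_real_,
    x = as.numeric(ab[, 1]), y = as.numeric(ab[, 2]), z = as.numeric(ab[, 3])
  )
  if (is.null(dim(bb)) && length(bb) >= 3) bb <- matrix(bb, nrow = 1)
  bondsDf <- if (!is.null(bb) && nrow(bb)) {
    data.frame(a1 = as.integer(bb[, 1]) - 1L,
               a2 = as.integer(bb[, 2]) - 1L,
               order = as.numeric(bb[, 3]))
  } else NULL

  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  rec <- lines[seq_len(which(grepl("^\\$\\$\\$\\$", lines))[1])]
  # formal charges: M  CHG  n  aaa vvv ...
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)),
                                "\\s+")[[1]])
    cnt <- toks[1]
    for (j in seq_len(cnt)) {
      atomsDf$formal_charge[toks[2 * j]] <- toks[2 * j + 1]
    }
  }
  # partial charges from the documented property field
  pcIdx <- grep("^>\\s+<PARTIAL_CHARGES>", rec)
  if (length(pcIdx)) {
    vals <- character()
    i <- pcIdx[1] + 1
    while (i <= length(rec) && nzchar(trimws(rec[i])) &&
           !grepl("^\\$\\$\\$\\$", rec[i])) {
      vals <- c(vals, trimws(rec[i]))
      i <- i + 1
    }
    if (length(vals) != n)
      stop("parse error: PARTIAL_CHARGES has ", length(vals),
           " values for ", n, " atoms", call. = FALSE)
    atomsDf$partial_charge <- as.numeric(vals)
  }
  if (is.null(name)) {
    title <- trimws(rec[1])
    name <- if (nzchar(title)) title else ""
  }
  molecularGraph(atomsDf, bondsDf, name = name,
                 netCharge = sum(atomsDf$formal_charge))
}

#' Write a molecule as an SDF V2000 record
#'
#' Writes the atom/bond blocks (atom ids renumbered 1..n in id order),
#' "M  CHG" lines for nonzero formal charges, and - when partial charges
#' are present - a PARTIAL_CHARGES data field with one value per atom line
#' (e units, 4 decimals).
#'
#' @param g a \linkS4class{MolecularGraph}
#' @param file path, connection, or "" for stdout; when \code{append=TRUE}
#'   records accumulate in one multi-molecule file.
#' @param append logical
#' @return invisibly, the record text.
#' @export
writeSDF <- function(g, file = "", append = FALSE) {
  at <- g@atoms
  bd <- g@bonds
  idx <- stats::setNames(seq_len(nrow(at)), at$id)
  num <- function(v) ifelse(is.na(v), 0, v)
  out <- c(
    g@name, "  fragcharge", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            nrow(at), nrow(bd)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            num(at$x), num(at$y), num(at$z), at$element)
  )
  if (nrow(bd))
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          idx[as.character(bd$a1)],
                          idx[as.character(bd$a2)], as.integer(bd$order)))
  chg <- which(at$formal_charge != 0)
  while (length(chg)) {
    take <- chg[seq_len(min(8, length(chg)))]
    chg <- setdiff(chg, take)
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(take)),
                         paste0(sprintf("%4d%4d", take,
                                        at$formal_charge[take]),
                                collapse = "")))
  }
  out <- c(out, "M  END")
  if (!anyNA(at$partial_charge)) {
    out <- c(out, "> <PARTIAL_CHARGES>",
             sprintf("%.4f", at$partial_charge), "")
  }
  if (any(at$cap)) {
    out <- c(out, "> <CAP_ATOMS>",
             paste(which(at$cap), collapse = " "), "")
  }
  out <- c(out, "$$$$")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.character(file) && !nzchar(file)) {
    cat(txt)
  } else {
    cat(txt, file = file, append = append)
  }
  invisible(txt)
}

# ---- fragment library JSON --------------------------------------------------

#' Build a FragmentLibrary from molecules
#'
#' @param molecules list of fully charged \linkS4class{MolecularGraph}
#' @param ids character library ids (default: molecule names, made unique)
#' @param schemaVersion schema version tag
#' @return a validated \linkS4class{FragmentLibrary}
#' @export
fragmentLibrary <- function(molecules, ids = NULL, schemaVersion = "1") {
  if (is(molecules, "MolecularGraph")) molecules <- list(molecules)
  if (is.null(ids)) {
    ids <- vapply(molecules, function(m) m@name, character(1))
    ids <- make.unique(ifelse(nzchar(ids), ids,
                              paste0("mol", seq_along(molecules))))
  }
  names(molecules) <- ids
  lib <- new("FragmentLibrary", entries = molecules,
             schemaVersion = schemaVersion)
  validObject(lib)
  lib
}

#' @rdname fragcharge-accessors
#' @export
setMethod("libraryIds", "FragmentLibrary", function(x) names(x@entries))
#' @rdname fragcharge-accessors
#' @export
setMethod("libEntry", "FragmentLibrary", function(x, id) {
  if (!id %in% names(x@entries))
    stop("unknown library id '", id, "'", call. = FALSE)
  x@entries[[id]]
})
#' @rdname fragcharge-accessors
#' @export
setMethod("numAtoms", "FragmentLibrary",
          function(x) vapply(x@entries, numAtoms, integer(1)))

setMethod("show", "FragmentLibrary", function(object) {
  cat(sprintf("FragmentLibrary (schema %s): %d entries\n",
              object@schemaVersion, length(object@entries)))
  for (id in utils::head(names(object@entries), 10)) {
    m <- object@entries[[id]]
    cat(sprintf("  %s: %s (%d atoms, net %g e)\n", id, m@name,
                numAtoms(m), m@netCharge))
  }
  if (length(object@entries) > 10) cat("  ...\n")
})

#' Write a fragment library to JSON
#'
#' Schema: \code{{"schema_version": "1", "entries": [{"library_id",
#' "name", "net_charge", "atoms": [{"id", "element", "charge", "cap"?}],
#' "bonds": [[a1, a2, order], ...]}]}}. Charges are written at full
#' precision so that write/read round-trips are identities.
#'
#' @param lib a \linkS4class{FragmentLibrary}
#' @param path output file
#' @return invisibly \code{path}
#' @export
writeFragmentLibrary <- function(lib, path) {
  stopifnot(is(lib, "FragmentLibrary"))
  entries <- lapply(names(lib@entries), function(id) {
    m <- lib@entries[[id]]
    at <- m@atoms
    atomsList <- lapply(seq_len(nrow(at)), function(i) {
      a <- list(id = at$id[i], element = at$element[i],
                charge = at$partial_charge[i])
      if (isTRUE(at$cap[i])) a$cap <- TRUE
      a
    })
    bondsList <- lapply(seq_len(nrow(m@bonds)), function(i)
      c(m@bonds$a1[i], m@bonds$a2[i], m@bonds$order[i]))
    list(library_id = id, name = m@name,
         net_charge = as.integer(round(m@netCharge)),
         atoms = atomsList, bonds = bondsList)
  })
  obj <- list(schema_version = lib@schemaVersion, entries = entries)
  # digits = I(17): doubles survive the round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a fragment library from JSON
#'
#' Validates the schema (see \code{\link{writeFragmentLibrary}}); entries
#' with atoms lacking a charge or duplicate library ids are rejected with a
#' JSON-pointer style location. An unknown schema version produces a
#' warning and a best-effort parse.
#'
#' @param path JSON file
#' @return a validated \linkS4class{FragmentLibrary}
#' @export
readFragmentLibrary <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("library parse error: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  ver <- obj$schema_version
  if (is.null(ver))
    stop("library schema violation at /schema_version: missing",
         call. = FALSE)
  if (!identical(as.character(ver), "1"))
    warning("unknown library schema version '", ver,
            "'; attempting best-effort parse")
  if (is.null(obj$entries))
    stop("library schema violation at /entries: missing", call. = FALSE)
  ids <- character()
  mols <- list()
  for (i in seq_along(obj$entries)) {
    e <- obj$entries[[i]]
    ptr <- sprintf("/entries/%d", i - 1)
    for (fld in c("library_id", "atoms", "bonds"))
      if (is.null(e[[fld]]))
        stop("library schema violation at ", ptr, "/", fld, ": missing",
             call. = FALSE)
    if (e$library_id %in% ids)
      stop("duplicate library_id '", e$library_id, "' at ", ptr,
           call. = FALSE)
    atRows <- lapply(seq_along(e$atoms), function(j) {
      a <- e$atoms[[j]]
      if (is.null(a$id) || is.null(a$element))
        stop("library schema violation at ", ptr, "/atoms/", j - 1,
             ": id/element missing", call. = FALSE)
      if (is.null(a$charge) || is.na(suppressWarnings(as.numeric(a$charge))))
        stop("library schema violation at ", ptr, "/atoms/", j - 1,
             ": atom has no partial charge", call. = FALSE)
      data.frame(id = as.integer(a$id), element = as.character(a$element),
                 partial_charge = as.numeric(a$charge),
                 cap = isTRUE(a$cap))
    })
    at <- do.call(rbind, atRows)
    bd <- if (length(e$bonds)) {
      do.call(rbind, lapply(seq_along(e$bonds), function(j) {
        b <- unlist(e$bonds[[j]])
        if (length(b) != 3)
          stop("library schema violation at ", ptr, "/bonds/", j - 1,
               ": expected [a1, a2, order]", call. = FALSE)
        data.frame(a1 = as.integer(b[1]), a2 = as.integer(b[2]),
                   order = as.numeric(b[3]))
      }))
    } else NULL
    nm <- if (!is.null(e$name)) e$name else e$library_id
    nc <- if (!is.null(e$net_charge)) as.numeric(e$net_charge) else
      sum(at$partial_charge)
    m <- tryCatch(molecularGraph(at, bd, name = nm, netCharge = nc),
                  error = function(err)
                    stop("library schema violation at ", ptr, ": ",
                         conditionMessage(err), call. = FALSE))
    ids <- c(ids, e$library_id)
    mols <- c(mols, m)
  }
  names(mols) <- ids
  lib <- new("FragmentLibrary", entries = mols,
             schemaVersion = as.character(ver))
  validObject(lib)
  lib
}
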