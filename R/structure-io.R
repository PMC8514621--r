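# residue identity: (chain, author number, insertion code), kept verbatim
# so Chothia numbering on antibody chains survives round trips
make_residue_key <- function(chain, resnum, icode = "") {
  icode[is.na(icode)] <- ""
  paste(chain, resnum, icode, sep = ":")
}

residue_keys <- function(structure) make_residue_key(structure$atoms$chain,
                                                     structure$atoms$resnum,
                                                     structure$atoms$icode)

new_structure <- function(atoms, chain_roles = NULL) {
  stopifnot(nrow(atoms) >= 1L)
  if (is.null(chain_roles)) {
    ch <- unique(atoms$chain)
    chain_roles <- setNames(rep("unassigned", length(ch)), ch)
  }
  structure(list(atoms = atoms, chain_roles = chain_roles),
            class = "zern_structure")
}

#' @export
print.zern_structure <- function(x, ...) {
  cat("Molecular structure:", nrow(x$atoms), "atoms,",
      length(unique(residue_keys(x))), "residues,",
      length(x$chain_roles), "chain(s)\n")
  roles <- paste0(names(x$chain_roles), "=", x$chain_roles, collapse = ", ")
  cat("  chain roles:", roles, "\n")
  invisible(x)
}

# split a residue field like "100A" into number and insertion code
split_resfield <- function(s) {
  m <- regmatches(s, regexec("^(-?[0-9]+)([A-Za-z]?)$", s))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(resnum = as.integer(m[2L]), icode = m[3L])
}

#' Read a PQR structure file
#'
#' Parses the whitespace-delimited PQR dialect (ATOM/HETATM records with
#' fields: serial, atom name, residue name, chain, residue number with
#' optional insertion code, x, y, z, partial charge, radius). Charges are
#' in elementary-charge units, coordinates and radii in Angstrom.
#'
#' @param path Path to a PQR file.
#' @return A \code{zern_structure} with all chain roles unassigned.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  ln_no <- which(rec)
  rows <- lapply(seq_along(ln_no), function(i) {
    ln <- lines[ln_no[i]]
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(f) < 10L)
      stop("malformed PQR record at line ", ln_no[i], ": expected 10 fields, got ",
           length(f))
    rf <- split_resfield(f[5L])
    if (length(f) >= 11L && !is.null(split_resfield(f[6L]))) {
      chain <- f[5L]; rf <- split_resfield(f[6L]); off <- 6L
    } else if (!is.null(rf)) {
      chain <- ""; off <- 5L
    } else stop("malformed PQR record at line ", ln_no[i],
                ": cannot parse residue field")
    num <- suppressWarnings(as.numeric(f[(off + 1L):(off + 5L)]))
    if (any(is.na(num)))
      stop("malformed PQR record at line ", ln_no[i],
           ": non-numeric coordinate/charge/radius field")
    if (length(f) < off + 5L)
      stop("malformed PQR record at line ", ln_no[i], ": missing charge or radius")
    data.frame(serial = as.integer(f[2L]), name = f[3L],
               element = guess_element(f[3L]), resname = f[4L],
               chain = chain, resnum = rf$resnum, icode = rf$icode,
               x = num[1L], y = num[2L], z = num[3L],
               charge = num[4L], radius = num[5L],
               het = startsWith(ln, "HETATM"),
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0))
    stop("PQR contains non-positive atomic radii")
  new_structure(atoms)
}

#' Write a structure in PQR format
#'
#' @param structure A \code{zern_structure}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pqr <- function(structure, path) {
  a <- structure$atoms
  rectype <- ifelse(a$het, "HETATM", "ATOM")
  lines <- sprintf("%s %d %s %s %s %s%s %.4f %.4f %.4f %.4f %.4f",
                   rectype, a$serial, a$name, a$resname, a$chain,
                   a$resnum, a$icode, a$x, a$y, a$z, a$charge, a$radius)
  writeLines(lines, path)
  invisible(path)
}

guess_element <- function(name) {
  e <- sub("^[0-9]*", "", name)
  e <- substr(e, 1L, 1L)
  toupper(e)
}

# Bondi-style van der Waals radii (Angstrom), used when a PDB file is read
# without explicit radii
default_radius_table <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

#' Read a PDB structure file
#'
#' Reads ATOM/HETATM records through \pkg{bio3d} and fills per-atom radii
#' and partial charges from lookup tables (PDB files carry neither).
#' Alternate-location duplicates are resolved by keeping the highest
#' occupancy record (first encountered on ties). Atoms missing from
#' \code{radius_table} get \code{default_radius} with a warning; atoms
#' missing from \code{charge_table} get charge 0.
#'
#' @param path Path to a PDB file.
#' @param radius_table Named numeric vector, element -> radius (Angstrom).
#' @param charge_table Named numeric vector, "RESNAME:ATOMNAME" -> charge
#'   (elementary charges), or \code{NULL} for all-zero charges.
#' @param default_radius Fallback radius in Angstrom (default 1.7).
#' @return A \code{zern_structure}.
#' @export
read_pdb <- function(path, radius_table = default_radius_table(),
                     charge_table = NULL, default_radius = 1.7) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0L) stop("empty structure: ", path)
  # altloc filter: keep the highest-occupancy alternative per atom site
  alt <- !is.na(a$alt) & a$alt != ""
  if (any(alt)) {
    site <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
    occ <- ifelse(is.na(a$o), 1, a$o)
    keep <- !logical(nrow(a))
    for (s in unique(site[alt])) {
      i <- which(site == s)
      if (length(i) > 1L) {
        best <- i[which.max(occ[i])]
        keep[setdiff(i, best)] <- FALSE
      }
    }
    a <- a[keep, , drop = FALSE]
  }
  elem <- toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                         guess_element(a$elety), a$elesy))
  rad <- unname(radius_table[elem])
  missing_r <- is.na(rad)
  if (any(missing_r)) {
    warning(sum(missing_r), " atom(s) missing from radius table; default ",
            default_radius, " A applied")
    rad[missing_r] <- default_radius
  }
  chg <- rep(0, nrow(a))
  if (!is.null(charge_table)) {
    key <- paste(a$resid, a$elety, sep = ":")
    hit <- key %in% names(charge_table)
    chg[hit] <- unname(charge_table[key[hit]])
  }
  icode <- ifelse(is.na(a$insert), "", a$insert)
  chain <- ifelse(is.na(a$chain), "", a$chain)
  atoms <- data.frame(serial = a$eleno, name = a$elety, element = elem,
                      resname = a$resid, chain = chain, resnum = a$resno,
                      icode = icode, x = a$x, y = a$y, z = a$z,
                      charge = chg, radius = rad,
                      het = a$type == "HETATM", stringsAsFactors = FALSE)
  new_structure(atoms)
}

#' Assign antibody/antigen roles to chains
#'
#' @param structure A \code{zern_structure}.
#' @param heavy Chain id of the antibody heavy chain (or \code{NULL}).
#' @param light Chain id of the antibody light chain (or \code{NULL}).
#' @param antigen Character vector of antigen chain ids.
#' @return The structure with \code{chain_roles} updated; unlisted chains
#'   stay \code{"unassigned"}.
#' @export
assign_chain_roles <- function(structure, heavy = NULL, light = NULL,
                               antigen = character(0)) {
  avail <- unique(structure$atoms$chain)
  wanted <- c(heavy, light, antigen)
  unknown <- setdiff(wanted, avail)
  if (length(unknown) > 0L)
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  roles <- setNames(rep("unassigned", length(avail)), avail)
  if (!is.null(heavy)) roles[heavy] <- "heavy"
  if (!is.null(light)) roles[light] <- "light"
  roles[antigen] <- "antigen"
  structure$chain_roles <- roles
  structure
}

# subset of a structure restricted to chains with the given role(s)
structure_subset <- function(structure, roles) {
  ch <- names(structure$chain_roles)[structure$chain_roles %in% roles]
  keep <- structure$atoms$chain %in% ch
  if (!any(keep)) stop("no atoms with role(s): ", paste(roles, collapse = ", "))
  new_structure(structure$atoms[keep, , drop = FALSE],
                structure$chain_roles[ch])
}

new_cloud <- function(df, probe = NA_real_, source = "computed") {
  stopifnot(nrow(df) >= 1L)
  structure(df, probe = probe, source = source,
            class = c("zern_cloud", "data.frame"))
}

#' Read a surface point cloud from text
#'
#' Rows of \code{x y z es_value [residue_key]}, whitespace-delimited.
#' When the residue column is absent, points carry an \code{NA} sentinel
#' key; patch operations that need residue identities refuse such clouds.
#'
#' @param path Path to the point-cloud file.
#' @return A \code{zern_cloud} (data frame with columns x, y, z, es,
#'   residue_key) with \code{source = "file"}.
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.table(path, header = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse point cloud ", path,
                                          ": ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty point cloud: ", path)
  if (ncol(df) < 4L) stop("point cloud needs at least 4 columns (x y z es)")
  for (j in 1:4) if (!is.numeric(df[[j]]))
    stop("non-numeric field in column ", j, " of ", path)
  out <- data.frame(x = df[[1L]], y = df[[2L]], z = df[[3L]], es = df[[4L]],
                    residue_key = if (ncol(df) >= 5L) as.character(df[[5L]])
                                  else NA_character_,
                    stringsAsFactors = FALSE)
  new_cloud(out, source = "file")
}

#' Write a surface point cloud as text
#'
#' @param cloud A \code{zern_cloud}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  df <- as.data.frame(cloud)
  cols <- c("x", "y", "z", "es")
  if (!all(is.na(df$residue_key))) cols <- c(cols, "residue_key")
  write.table(format(df[cols], digits = 10, trim = TRUE), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

cloud_requires_keys <- function(cloud, what) {
  if (any(is.na(cloud$residue_key)))
    stop(what, " requires a point cloud with residue identities ",
         "(this cloud has sentinel keys)")
  invisible(TRUE)
}
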