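## ---------------------------------------------------------------------------
## AMBER prmtop dialect
## ---------------------------------------------------------------------------

fmt_chunk <- function(x, per_line, each_fmt) {
  if (length(x) == 0) return("")
  s <- sprintf(each_fmt, x)
  lines <- character(0)
  for (start in seq(1, length(s), by = per_line))
    lines <- c(lines, paste(s[start:min(start + per_line - 1, length(s))], collapse = ""))
  lines
}

prmtop_section <- function(flag, fmt_label, lines) {
  c(sprintf("%%FLAG %s", flag), sprintf("%%FORMAT(%s)", fmt_label), lines)
}

mass_is_h <- function(topology) topology$atoms$mass < 3

element_from_mass <- function(mass) {
  tab <- c(H = 1.008, C = 12.01, N = 14.01, O = 16.00, S = 32.06, P = 30.97)
  names(tab)[apply(abs(outer(mass, tab, "-")), 1, which.min)]
}

atomic_number <- function(element) {
  z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)
  out <- z[element]
  out[is.na(out)] <- 0
  as.integer(out)
}

#' Write a topology as an AMBER prmtop file
#'
#' Emits the FORTRAN-format sections needed to round-trip the [topology()]
#' data model (POINTERS, CHARGE with the 18.2223 internal scaling, MASS,
#' atom-type based Lennard-Jones ACOEF/BCOEF tables, bonded-parameter and
#' bonded-term sections split by hydrogen content, per-dihedral SCEE/SCNB
#' scale factors, the excluded-atoms list, residue labels and AMBER atom
#' types).  Bond/angle/dihedral parameters are deduplicated into parameter
#' tables as the format requires; 1-4 pairs are encoded through the dihedral
#' third-atom sign convention.
#'
#' @param topology a [topology()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_prmtop <- function(topology, path) {
  at <- topology$atoms
  n <- nrow(at)
  types <- unique(at$type)
  ntypes <- length(types)
  tidx <- match(at$type, types)
  ish <- mass_is_h(topology)

  ## parameter tables
  dedup <- function(m) {
    key <- apply(m, 1, paste, collapse = "|")
    uk <- !duplicated(key)
    list(tab = m[uk, , drop = FALSE], idx = match(key, key[uk]))
  }
  bt <- dedup(cbind(topology$bonds$kb, topology$bonds$r0))
  an <- dedup(cbind(topology$angles$kth, topology$angles$th0))
  dt <- dedup(cbind(topology$dihedrals$vn2, topology$dihedrals$per,
                    topology$dihedrals$phase))

  ## LJ tables (Lorentz-Berthelot on the per-type parameters)
  ljp <- topology$lj[match(types, topology$lj$type), ]
  npair <- ntypes * (ntypes + 1) / 2
  acoef <- bcoef <- numeric(npair)
  ico <- integer(ntypes * ntypes)
  for (i in seq_len(ntypes)) for (j in seq_len(ntypes)) {
    a <- min(i, j); b <- max(i, j)
    k <- a + b * (b - 1) / 2
    ico[(i - 1) * ntypes + j] <- k
    rmin <- ljp$rmin_half[a] + ljp$rmin_half[b]
    eps <- sqrt(ljp$eps[a] * ljp$eps[b])
    acoef[k] <- eps * rmin^12
    bcoef[k] <- 2 * eps * rmin^6
  }

  ## bonded term encodings (coordinate-array indices: (atom-1)*3)
  enc <- function(i) (i - 1L) * 3L
  b <- topology$bonds; bh <- ish[b$i] | ish[b$j]
  a <- topology$angles; ah <- ish[a$i] | ish[a$j] | ish[a$k]
  d <- topology$dihedrals
  ## 1-4 ownership: the first dihedral term over a (i,l) pair that is a real
  ## 1-4 pair keeps a positive third index; all others are marked negative
  key <- function(i, j) pmin(i, j) * (n + 1L) + pmax(i, j)
  p14 <- key(topology$pairs14$i, topology$pairs14$j)
  dk <- key(d$i, d$l)
  owns14 <- (dk %in% p14) & !duplicated(dk)
  ## a negative-k encoding needs k != 1; reverse the quadruple in that case
  flip <- !owns14 & d$k == 1
  for (cols in list(c("i", "l"), c("j", "k"))) {
    tmp <- d[[cols[1]]][flip]; d[[cols[1]]][flip] <- d[[cols[2]]][flip]
    d[[cols[2]]][flip] <- tmp
  }
  dh <- ish[d$i] | ish[d$j] | ish[d$k] | ish[d$l]
  enc_d <- function(rows) {
    if (!length(rows)) return(integer(0))
    kk <- enc(d$k[rows]); kk[!owns14[rows]] <- -kk[!owns14[rows]]
    as.integer(t(cbind(enc(d$i[rows]), enc(d$j[rows]), kk, enc(d$l[rows]),
                       dt$idx[rows])))
  }
  enc_b <- function(df, rows, idx)
    as.integer(t(cbind(enc(df$i[rows]), enc(df$j[rows]), idx[rows])))
  enc_a <- function(df, rows, idx)
    as.integer(t(cbind(enc(df$i[rows]), enc(df$j[rows]), enc(df$k[rows]), idx[rows])))

  ## excluded atoms list (1-2, 1-3 and 1-4, AMBER convention)
  exall <- rbind(topology$excl[, c("i", "j")], topology$pairs14[, c("i", "j")])
  nexc <- integer(n); exlist <- integer(0)
  for (i in seq_len(n)) {
    js <- sort(c(exall$j[exall$i == i], exall$i[exall$j == i]))
    js <- js[js > i]
    if (length(js) == 0) js <- 0L
    nexc[i] <- length(js)
    exlist <- c(exlist, js)
  }

  res_ids <- unique(at$res_id)
  res_ptr <- match(res_ids, at$res_id)
  res_lab <- at$res_name[res_ptr]

  ptr <- integer(31)
  ptr[1] <- n; ptr[2] <- ntypes
  ptr[3] <- sum(bh); ptr[4] <- sum(!bh)
  ptr[5] <- sum(ah); ptr[6] <- sum(!ah)
  ptr[7] <- sum(dh); ptr[8] <- sum(!dh)
  ptr[11] <- length(exlist); ptr[12] <- length(res_ids)
  ptr[13] <- sum(!bh); ptr[14] <- sum(!ah); ptr[15] <- sum(!dh)
  ptr[16] <- nrow(bt$tab); ptr[17] <- nrow(an$tab); ptr[18] <- nrow(dt$tab)
  ptr[19] <- ntypes

  E <- "5E16.8"; I <- "10I8"; A <- "20a4"
  fe <- function(x) fmt_chunk(x, 5, "%16.8E")
  fi <- function(x) fmt_chunk(x, 10, "%8d")
  fa <- function(x) fmt_chunk(substr(sprintf("%-4s", x), 1, 4), 20, "%s")

  out <- c(
    "%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/26  00:00:00",
    prmtop_section("TITLE", A, fa(substr(topology$title, 1, 76))),
    prmtop_section("POINTERS", I, fi(ptr)),
    prmtop_section("ATOM_NAME", A, fa(at$name)),
    prmtop_section("CHARGE", E, fe(at$charge * PRMTOP_CHARGE_SCALE)),
    prmtop_section("ATOMIC_NUMBER", I, fi(atomic_number(at$element))),
    prmtop_section("MASS", E, fe(at$mass)),
    prmtop_section("ATOM_TYPE_INDEX", I, fi(tidx)),
    prmtop_section("NUMBER_EXCLUDED_ATOMS", I, fi(nexc)),
    prmtop_section("NONBONDED_PARM_INDEX", I, fi(ico)),
    prmtop_section("RESIDUE_LABEL", A, fa(res_lab)),
    prmtop_section("RESIDUE_POINTER", I, fi(res_ptr)),
    prmtop_section("BOND_FORCE_CONSTANT", E, fe(bt$tab[, 1])),
    prmtop_section("BOND_EQUIL_VALUE", E, fe(bt$tab[, 2])),
    prmtop_section("ANGLE_FORCE_CONSTANT", E, fe(an$tab[, 1])),
    prmtop_section("ANGLE_EQUIL_VALUE", E, fe(an$tab[, 2])),
    prmtop_section("DIHEDRAL_FORCE_CONSTANT", E, fe(dt$tab[, 1])),
    prmtop_section("DIHEDRAL_PERIODICITY", E, fe(dt$tab[, 2])),
    prmtop_section("DIHEDRAL_PHASE", E, fe(dt$tab[, 3])),
    prmtop_section("SCEE_SCALE_FACTOR", E,
                   fe(rep(topology$scee, nrow(dt$tab)))),
    prmtop_section("SCNB_SCALE_FACTOR", E,
                   fe(rep(topology$scnb, nrow(dt$tab)))),
    prmtop_section("LENNARD_JONES_ACOEF", E, fe(acoef)),
    prmtop_section("LENNARD_JONES_BCOEF", E, fe(bcoef)),
    prmtop_section("BONDS_INC_HYDROGEN", I, fi(enc_b(b, which(bh), bt$idx))),
    prmtop_section("BONDS_WITHOUT_HYDROGEN", I, fi(enc_b(b, which(!bh), bt$idx))),
    prmtop_section("ANGLES_INC_HYDROGEN", I, fi(enc_a(a, which(ah), an$idx))),
    prmtop_section("ANGLES_WITHOUT_HYDROGEN", I, fi(enc_a(a, which(!ah), an$idx))),
    prmtop_section("DIHEDRALS_INC_HYDROGEN", I, fi(enc_d(which(dh)))),
    prmtop_section("DIHEDRALS_WITHOUT_HYDROGEN", I, fi(enc_d(which(!dh)))),
    prmtop_section("EXCLUDED_ATOMS_LIST", I, fi(exlist)),
    prmtop_section("AMBER_ATOM_TYPE", A, fa(at$type))
  )
  writeLines(out, path)
  invisible(path)
}

parse_prmtop_sections <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%VERSION") & !startsWith(lines, "%COMMENT")]
  starts <- which(startsWith(lines, "%FLAG"))
  if (length(starts) == 0) stop("parse error: no %FLAG sections found in ", path)
  sections <- list()
  for (s in seq_along(starts)) {
    from <- starts[s]
    to <- if (s < length(starts)) starts[s + 1] - 1 else length(lines)
    flag <- trimws(sub("^%FLAG", "", lines[from]))
    fmt <- trimws(sub("^%FORMAT", "", lines[from + 1]))
    body <- lines[(from + 2):to]
    if (grepl("a", fmt, ignore.case = TRUE)) {
      width <- as.integer(sub(".*?([0-9]+)[aA]([0-9]+).*", "\\2", fmt))
      vals <- unlist(lapply(body, function(ln) {
        if (nchar(ln) == 0) return(character(0))
        trimws(substring(ln, seq(1, nchar(ln), by = width),
                         pmin(seq(width, nchar(ln) + width - 1, by = width), nchar(ln))))
      }))
      vals <- vals[vals != ""]
    } else {
      vals <- as.numeric(unlist(strsplit(trimws(paste(body, collapse = " ")), "\\s+")))
      vals <- vals[!is.na(vals)]
    }
    sections[[flag]] <- vals
  }
  sections
}

#' Read an AMBER prmtop file
#'
#' Parses the FORTRAN-format sections into a [topology()].  Charges are
#' normalized from the internal 18.2223 scaling back to electron charges
#' (read this once: prmtop stores `q * 18.2223`, so testers must not scale
#' twice).  Per-type Lennard-Jones parameters are recovered from the
#' diagonal ACOEF/BCOEF entries; exclusion and 1-4 lists are regenerated
#' from the bond connectivity (topological distance), with per-dihedral
#' SCEE/SCNB factors applied to the corresponding 1-4 pairs when the file
#' carries them and the global defaults (1.2 / 2.0) otherwise.  Unknown
#' sections are ignored with a warning; CMAP and extra-point sections are
#' rejected.
#'
#' @param path prmtop file path.
#' @return a [topology()].
#' @export
read_prmtop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sec <- parse_prmtop_sections(path)
  if (any(grepl("^CMAP|^LESTYPE|EXTRA_POINT", names(sec))))
    stop("unsupported prmtop: CMAP/extra-point sections are not part of the data model")
  mandatory <- c("POINTERS", "ATOM_NAME", "CHARGE", "MASS", "ATOM_TYPE_INDEX",
                 "NONBONDED_PARM_INDEX", "LENNARD_JONES_ACOEF",
                 "LENNARD_JONES_BCOEF", "AMBER_ATOM_TYPE",
                 "BOND_FORCE_CONSTANT", "BOND_EQUIL_VALUE",
                 "ANGLE_FORCE_CONSTANT", "ANGLE_EQUIL_VALUE",
                 "DIHEDRAL_FORCE_CONSTANT", "DIHEDRAL_PERIODICITY",
                 "DIHEDRAL_PHASE", "BONDS_INC_HYDROGEN",
                 "BONDS_WITHOUT_HYDROGEN", "ANGLES_INC_HYDROGEN",
                 "ANGLES_WITHOUT_HYDROGEN", "DIHEDRALS_INC_HYDROGEN",
                 "DIHEDRALS_WITHOUT_HYDROGEN", "RESIDUE_LABEL",
                 "RESIDUE_POINTER")
  miss <- setdiff(mandatory, names(sec))
  if (length(miss))
    stop("parse error: missing mandatory prmtop section(s): ",
         paste(miss, collapse = ", "))
  known <- c(mandatory, "TITLE", "ATOMIC_NUMBER", "NUMBER_EXCLUDED_ATOMS",
             "EXCLUDED_ATOMS_LIST", "SCEE_SCALE_FACTOR", "SCNB_SCALE_FACTOR",
             "HBOND_ACOEF", "HBOND_BCOEF", "HBCUT", "SOLTY", "RADIUS_SET",
             "RADII", "SCREEN", "IPOL", "TREE_CHAIN_CLASSIFICATION",
             "JOIN_ARRAY", "IROTAT", "BOX_DIMENSIONS")
  unknown <- setdiff(names(sec), known)
  if (length(unknown))
    warning("ignoring unknown prmtop section(s): ", paste(unknown, collapse = ", "))

  ptr <- as.integer(sec$POINTERS)
  n <- ptr[1]; ntypes <- ptr[2]
  if (length(sec$ATOM_NAME) != n || length(sec$CHARGE) != n || length(sec$MASS) != n)
    stop("validation error: per-atom section lengths inconsistent with NATOM")
  mass <- sec$MASS
  element <- if (!is.null(sec$ATOMIC_NUMBER)) {
    z <- as.integer(sec$ATOMIC_NUMBER)
    names_z <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
                 "Na", "Mg", "Al", "Si", "P", "S", "Cl")
    ifelse(z >= 1 & z <= length(names_z), names_z[pmax(z, 1)], "X")
  } else element_from_mass(mass)

  res_ptr <- as.integer(sec$RESIDUE_POINTER)
  res_id <- findInterval(seq_len(n), res_ptr)
  res_name <- sec$RESIDUE_LABEL[res_id]

  tidx <- as.integer(sec$ATOM_TYPE_INDEX)
  type_label <- character(ntypes)
  for (t in seq_len(ntypes)) type_label[t] <- sec$AMBER_ATOM_TYPE[match(t, tidx)]
  ## diagonal LJ entries -> Rmin/2, eps
  ico <- as.integer(sec$NONBONDED_PARM_INDEX)
  rmin_half <- eps <- numeric(ntypes)
  for (t in seq_len(ntypes)) {
    k <- ico[(t - 1) * ntypes + t]
    A <- sec$LENNARD_JONES_ACOEF[k]; B <- sec$LENNARD_JONES_BCOEF[k]
    if (A > 0 && B > 0) {
      rmin_half[t] <- (2 * A / B)^(1 / 6) / 2
      eps[t] <- B^2 / (4 * A)
    }
  }
  atoms <- data.frame(name = sec$ATOM_NAME[seq_len(n)], element = element,
                      type = type_label[tidx], mass = mass,
                      charge = sec$CHARGE / PRMTOP_CHARGE_SCALE,
                      res_id = res_id, res_name = res_name,
                      stringsAsFactors = FALSE)
  lj <- data.frame(type = type_label, rmin_half = rmin_half, eps = eps,
                   stringsAsFactors = FALSE)

  dec <- function(v) as.integer(abs(v) / 3) + 1L
  read_terms <- function(flagA, flagB, width) {
    v <- c(sec[[flagA]], sec[[flagB]])
    if (length(v) == 0) return(matrix(numeric(0), 0, width + 1))
    matrix(v, ncol = width + 1, byrow = TRUE)
  }
  bm <- read_terms("BONDS_INC_HYDROGEN", "BONDS_WITHOUT_HYDROGEN", 2)
  am <- read_terms("ANGLES_INC_HYDROGEN", "ANGLES_WITHOUT_HYDROGEN", 3)
  dm <- read_terms("DIHEDRALS_INC_HYDROGEN", "DIHEDRALS_WITHOUT_HYDROGEN", 4)
  chk_idx <- function(m, cols, what) {
    if (nrow(m) == 0) return()
    ai <- dec(m[, cols])
    if (any(ai < 1 | ai > n))
      stop(sprintf("validation error: %s term references atom index beyond atom count (%d)",
                   what, n))
  }
  chk_idx(bm, 1:2, "bond"); chk_idx(am, 1:3, "angle"); chk_idx(dm, 1:4, "dihedral")
  bonds <- data.frame(i = dec(bm[, 1]), j = dec(bm[, 2]),
                      kb = sec$BOND_FORCE_CONSTANT[bm[, 3]],
                      r0 = sec$BOND_EQUIL_VALUE[bm[, 3]])
  angles <- data.frame(i = dec(am[, 1]), j = dec(am[, 2]), k = dec(am[, 3]),
                       kth = sec$ANGLE_FORCE_CONSTANT[am[, 4]],
                       th0 = sec$ANGLE_EQUIL_VALUE[am[, 4]])
  dihedrals <- data.frame(i = dec(dm[, 1]), j = dec(dm[, 2]), k = dec(dm[, 3]),
                          l = dec(dm[, 4]),
                          vn2 = sec$DIHEDRAL_FORCE_CONSTANT[dm[, 5]],
                          per = abs(sec$DIHEDRAL_PERIODICITY[dm[, 5]]),
                          phase = sec$DIHEDRAL_PHASE[dm[, 5]])

  ## scale divisors: per-dihedral if the file has them, else global defaults
  scee <- DEFAULT_SCEE; scnb <- DEFAULT_SCNB
  top <- topology(atoms, lj, bonds, angles, dihedrals, scee = scee, scnb = scnb,
                  title = if (!is.null(sec$TITLE)) paste(sec$TITLE, collapse = " ")
                          else "prmtop import")
  if (!is.null(sec$SCEE_SCALE_FACTOR) && nrow(dm) > 0) {
    key <- function(i, j) pmin(i, j) * (n + 1L) + pmax(i, j)
    dk <- key(dec(dm[, 1]), dec(dm[, 4]))
    pk <- key(top$pairs14$i, top$pairs14$j)
    m <- match(pk, dk)
    ok <- !is.na(m)
    top$pairs14$scee[ok] <- sec$SCEE_SCALE_FACTOR[dm[m[ok], 5]]
    top$pairs14$scnb[ok] <- sec$SCNB_SCALE_FACTOR[dm[m[ok], 5]]
  }
  v <- validate_topology(top)
  if (length(v)) stop("validation error reading ", path, ": ",
                      paste(v, collapse = "; "))
  top
}

## ---------------------------------------------------------------------------
## native plain-text dialect
## ---------------------------------------------------------------------------

#' Write a topology in the native plain-text dialect
#'
#' Human-readable key-value format with one section per term class, numeric
#' fields printed at full double precision (%.17g) so a write/read cycle is
#' value-exact.  Angles and phases are stored in radians, the internal unit.
#' Section order is insignificant on read.
#'
#' @param topology a [topology()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_native_topology <- function(topology, path) {
  g <- function(x) sprintf("%.17g", x)
  at <- topology$atoms
  out <- c("# qmmlink native topology v1",
           paste("title", topology$title),
           paste("scee", g(topology$scee)),
           paste("scnb", g(topology$scnb)),
           "[atoms]",
           "# index name element type mass charge res_id res_name",
           sprintf("%d %s %s %s %s %s %d %s", seq_len(nrow(at)), at$name,
                   at$element, at$type, g(at$mass), g(at$charge),
                   at$res_id, at$res_name),
           "[lj]",
           "# type rmin_half eps",
           sprintf("%s %s %s", topology$lj$type, g(topology$lj$rmin_half),
                   g(topology$lj$eps)),
           "[bonds]",
           "# i j kb r0",
           sprintf("%d %d %s %s", topology$bonds$i, topology$bonds$j,
                   g(topology$bonds$kb), g(topology$bonds$r0)),
           "[angles]",
           "# i j k kth th0_rad",
           sprintf("%d %d %d %s %s", topology$angles$i, topology$angles$j,
                   topology$angles$k, g(topology$angles$kth), g(topology$angles$th0)),
           "[dihedrals]",
           "# i j k l vn2 per phase_rad",
           sprintf("%d %d %d %d %s %s %s", topology$dihedrals$i,
                   topology$dihedrals$j, topology$dihedrals$k,
                   topology$dihedrals$l, g(topology$dihedrals$vn2),
                   g(topology$dihedrals$per), g(topology$dihedrals$phase)),
           "[exclusions]",
           "# i j",
           sprintf("%d %d", topology$excl$i, topology$excl$j),
           "[pairs14]",
           "# i j scee scnb",
           sprintf("%d %d %s %s", topology$pairs14$i, topology$pairs14$j,
                   g(topology$pairs14$scee), g(topology$pairs14$scnb)))
  writeLines(out, path)
  invisible(path)
}

#' Read a topology in the native plain-text dialect
#'
#' @param path file path.
#' @return a [topology()].
#' @export
read_native_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  title <- "native import"; scee <- DEFAULT_SCEE; scnb <- DEFAULT_SCNB
  sect <- NA_character_
  body <- list(atoms = character(), lj = character(), bonds = character(),
               angles = character(), dihedrals = character(),
               exclusions = character(), pairs14 = character())
  for (ln in lines) {
    if (startsWith(ln, "[")) { sect <- gsub("\\[|\\]", "", ln); next }
    if (is.na(sect)) {
      kv <- strsplit(ln, "\\s+")[[1]]
      if (kv[1] == "title") title <- paste(kv[-1], collapse = " ")
      else if (kv[1] == "scee") scee <- as.numeric(kv[2])
      else if (kv[1] == "scnb") scnb <- as.numeric(kv[2])
      next
    }
    if (!sect %in% names(body)) stop("parse error: unknown native section [", sect, "]")
    body[[sect]] <- c(body[[sect]], ln)
  }
  if (length(body$atoms) == 0) stop("parse error: missing [atoms] section")
  tok <- function(x) do.call(rbind, strsplit(x, "\\s+"))
  atm <- tok(body$atoms)
  atoms <- data.frame(name = atm[, 2], element = atm[, 3], type = atm[, 4],
                      mass = as.numeric(atm[, 5]), charge = as.numeric(atm[, 6]),
                      res_id = as.integer(atm[, 7]), res_name = atm[, 8],
                      stringsAsFactors = FALSE)
  ljm <- tok(body$lj)
  lj <- data.frame(type = ljm[, 1], rmin_half = as.numeric(ljm[, 2]),
                   eps = as.numeric(ljm[, 3]), stringsAsFactors = FALSE)
  num_df <- function(x, nm, int = seq_along(nm) <= 0) {
    if (length(x) == 0) {
      out <- as.data.frame(setNames(rep(list(numeric(0)), length(nm)), nm))
      return(out)
    }
    m <- tok(x)
    out <- as.data.frame(lapply(seq_along(nm), function(c) as.numeric(m[, c])))
    names(out) <- nm
    out
  }
  bonds <- num_df(body$bonds, c("i", "j", "kb", "r0"))
  angles <- num_df(body$angles, c("i", "j", "k", "kth", "th0"))
  dihedrals <- num_df(body$dihedrals, c("i", "j", "k", "l", "vn2", "per", "phase"))
  excl <- num_df(body$exclusions, c("i", "j"))
  pairs14 <- num_df(body$pairs14, c("i", "j", "scee", "scnb"))
  for (cl in c("i", "j")) { excl[[cl]] <- as.integer(excl[[cl]]); pairs14[[cl]] <- as.integer(pairs14[[cl]]) }
  for (cl in c("i", "j")) bonds[[cl]] <- as.integer(bonds[[cl]])
  for (cl in c("i", "j", "k")) angles[[cl]] <- as.integer(angles[[cl]])
  for (cl in c("i", "j", "k", "l")) dihedrals[[cl]] <- as.integer(dihedrals[[cl]])
  top <- topology(atoms, lj, bonds, angles, dihedrals, excl = excl,
                  pairs14 = pairs14, scee = scee, scnb = scnb, title = title)
  v <- validate_topology(top)
  if (length(v)) stop("validation error reading ", path, ": ",
                      paste(v, collapse = "; "))
  top
}

#' Read or write a topology, choosing the dialect
#'
#' @param path file path.
#' @param dialect `"prmtop"`, `"native"`, or `"auto"` (sniff the first line
#'   on read; choose by file extension `.prmtop`/`.parm7` on write).
#' @return [read_topology()]: a [topology()]; [write_topology()]: `path`.
#' @export
read_topology <- function(path, dialect = c("auto", "prmtop", "native")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1)
    dialect <- if (startsWith(first, "%VERSION") || startsWith(first, "%FLAG"))
      "prmtop" else "native"
  }
  if (dialect == "prmtop") read_prmtop(path) else read_native_topology(path)
}

#' @rdname read_topology
#' @param topology a [topology()] object.
#' @export
write_topology <- function(topology, path, dialect = c("auto", "prmtop", "native")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(prmtop|parm7|top)$", path)) "prmtop" else "native"
  if (dialect == "prmtop") write_prmtop(topology, path)
  else write_native_topology(topology, path)
}

## ---------------------------------------------------------------------------
## coordinates
## ---------------------------------------------------------------------------

#' Coordinate file I/O (AMBER restart and XYZ)
#'
#' `write_inpcrd`/`read_inpcrd` handle the AMBER ASCII restart format
#' (title, atom count, 6F12.7 coordinates); `write_xyz`/`read_xyz` the plain
#' XYZ format (count, comment, `element x y z`).  All in Angstrom.
#'
#' @param structure n x 3 coordinate matrix.
#' @param path file path.
#' @param title title line.
#' @param elements element symbols for XYZ output.
#' @return writers return `path` invisibly; readers an n x 3 matrix (XYZ
#'   reader: with attribute `elements`).
#' @name coordinate-io
NULL

#' @rdname coordinate-io
#' @export
write_inpcrd <- function(structure, path, title = "qmmlink coordinates") {
  x <- as.matrix(structure)
  flat <- as.vector(t(x))
  out <- c(title, sprintf("%6d", nrow(x)), fmt_chunk(flat, 6, "%12.7f"))
  writeLines(out, path)
  invisible(path)
}

#' @rdname coordinate-io
#' @export
read_inpcrd <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]][1])
  vals <- as.numeric(unlist(strsplit(trimws(paste(lines[-(1:2)], collapse = " ")),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) < 3 * n) stop("inpcrd has fewer coordinates than declared")
  matrix(vals[seq_len(3 * n)], ncol = 3, byrow = TRUE)
}

#' @rdname coordinate-io
#' @export
write_xyz <- function(structure, elements, path, title = "qmmlink") {
  x <- as.matrix(structure)
  out <- c(sprintf("%d", nrow(x)), title,
           sprintf("%-2s %18.10f %18.10f %18.10f", elements, x[, 1], x[, 2], x[, 3]))
  writeLines(out, path)
  invisible(path)
}

#' @rdname coordinate-io
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  tok <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  m <- t(vapply(tok, function(v) as.numeric(v[2:4]), numeric(3)))
  attr(m, "elements") <- vapply(tok, `[[`, character(1), 1)
  m
}
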