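#' Subunit assignment for a tetrameric channel
#'
#' Maps chain ids to GIRK subunit types. Heterotetramer analyses require
#' exactly four chains with at least one GIRK1 subunit. The arrangement of
#' subunits around the pore is not fixed by structure alone, so it is
#' user-supplied; [default_assignment()] gives the alternating arrangement
#' (GIRK1 on the diagonal) conventionally assumed for GIRK1/2 and GIRK1/4.
#'
#' @param map named character vector, `chain id -> subunit type`, subunit
#'   types among `"GIRK1"`, `"GIRK2"`, `"GIRK4"`.
#' @param require_tetramer enforce the four-chain / at-least-one-GIRK1
#'   invariant (default TRUE; disable for single-helix fixtures).
#' @return A `SubunitAssignment` (named character vector).
#' @export
subunit_assignment <- function(map, require_tetramer = TRUE) {
  map <- unlist(map)
  bad <- setdiff(unique(map), c("GIRK1", "GIRK2", "GIRK4"))
  if (length(bad)) {
    stop("unknown subunit type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(map)) || any(names(map) == "")) {
    stop("assignment must be a named chain -> subunit map", call. = FALSE)
  }
  if (require_tetramer) {
    if (length(map) != 4) {
      stop("channel analysis requires exactly 4 assigned chains, got ",
           length(map), call. = FALSE)
    }
    if (!any(map == "GIRK1")) {
      stop("heteromer assignment requires at least one GIRK1 chain",
           call. = FALSE)
    }
  }
  structure(map, class = "SubunitAssignment")
}

#' @param chains four chain ids, in pore order.
#' @param partner the non-GIRK1 subunit, `"GIRK2"` or `"GIRK4"`.
#' @rdname subunit_assignment
#' @export
default_assignment <- function(chains = c("A", "B", "C", "D"),
                               partner = c("GIRK2", "GIRK4")) {
  partner <- match.arg(partner)
  map <- rep(c("GIRK1", partner), 2)
  names(map) <- chains
  subunit_assignment(map)
}

#' Functional residue roles with canonical numbering
#'
#' The packaged defaults name the residues and helix segments used by all
#' analyses, in 1-based canonical UniProt numbering per subunit: the
#' helix-bundle-crossing (HBC) gate phenylalanines, the G-loop gate girdle
#' methionines, the TM2 hinge glycines, the PIP2-coordinating lysines, the
#' TM1 hydrophobic wire, pore-helix and slide-helix residues, and the TM1 /
#' slide-helix / pore-helix / TM2 segment ranges.
#'
#' @return A `ResidueRoleMap`: named list of roles, each a named list of
#'   `subunit -> integer residue indices`.
#' @export
default_role_map <- function() {
  structure(list(
    "HBC-gate"          = list(GIRK1 = 181L, GIRK2 = 192L),
    "G-loop-gate"       = list(GIRK2 = c(313L, 319L)),
    "hinge-glycine"     = list(GIRK1 = 169L, GIRK2 = 180L, GIRK4 = 175L),
    "PIP2-lysines"      = list(GIRK1 = c(183L, 188L, 189L),
                               GIRK2 = c(194L, 199L, 200L),
                               GIRK4 = c(189L, 194L, 195L)),
    "TM1-wire"          = list(GIRK1 = c(87L, 91L, 95L)),
    "pore-helix-pair"   = list(GIRK1 = c(137L, 141L)),
    "TM2-acidic"        = list(GIRK1 = 173L),
    "pre-gate-Met"      = list(GIRK1 = 180L),
    "SH-acids"          = list(GIRK1 = c(70L, 77L)),
    "CD-loop"           = list(GIRK2 = c(230L, 233L)),
    "G-loop-pair"       = list(GIRK1 = c(188L, 313L), GIRK2 = 315L),
    "ligand-site-source" = list(GIRK1 = 97L),
    "TM1"               = list(GIRK1 = 82:105),
    "SH"                = list(GIRK1 = 67:76),
    "PH"                = list(GIRK1 = 130:142),
    "TM2-outer"         = list(GIRK1 = 158:162),
    "TM2-pivot"         = list(GIRK1 = 167:169),
    "TM2-inner"         = list(GIRK1 = 174:178)
  ), class = "ResidueRoleMap")
}

#' Look up the canonical residue indices of a role for one subunit
#'
#' Role offsets are exact integer arithmetic; e.g. the HBC gate residue
#' minus the hinge glycine of the same subunit gives the conserved i-12
#' register.
#'
#' @param roles a `ResidueRoleMap` (see [default_role_map()]).
#' @param role_name role to look up.
#' @param subunit `"GIRK1"`, `"GIRK2"` or `"GIRK4"`.
#' @return Integer residue indices.
#' @export
lookup_role <- function(roles, role_name, subunit) {
  entry <- roles[[role_name]]
  if (is.null(entry)) {
    stop("undefined role: '", role_name, "'", call. = FALSE)
  }
  res <- entry[[subunit]]
  if (is.null(res)) {
    stop("role '", role_name, "' is not defined for subunit '", subunit,
         "'", call. = FALSE)
  }
  as.integer(res)
}

#' Read a role map or subunit assignment from a key-value text file
#'
#' Lines are `key = value`; assignment keys are chain ids with a subunit
#' value; role keys are `role/subunit` with a comma- or range- (`a-b`)
#' valued residue list. `#` starts a comment.
#'
#' @param path configuration file.
#' @return list with `assignment` (or NULL) and `roles` (defaults overlaid
#'   with any entries in the file).
#' @export
read_role_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- sub("#.*$", "", readLines(path))
  lines <- trimws(lines[trimws(lines) != ""])
  roles <- unclass(default_role_map())
  assign_map <- character()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (grepl("/", key, fixed = TRUE)) {
      rs <- strsplit(key, "/", fixed = TRUE)[[1]]
      ids <- unlist(lapply(strsplit(val, ",")[[1]], function(tok) {
        tok <- trimws(tok)
        if (grepl("-", tok)) {
          ab <- as.integer(strsplit(tok, "-")[[1]])
          ab[1]:ab[2]
        } else as.integer(tok)
      }))
      roles[[rs[1]]][[rs[2]]] <- ids
    } else {
      assign_map[key] <- val
    }
  }
  list(assignment = if (length(assign_map))
    subunit_assignment(assign_map) else NULL,
    roles = structure(roles, class = "ResidueRoleMap"))
}
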