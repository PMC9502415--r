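## Atom selection: a resolved, ordered index list into Topology$atoms plus
## the source expression, and the small selector grammar shared by the
## user-facing analyses.

BACKBONE_NAMES <- c("N", "CA", "C", "O")

is_hydrogen <- function(atoms) {
  toupper(atoms$element) == "H" | grepl("^[0-9]*H", atoms$name)
}

atom_scope_mask <- function(atoms, scope) {
  switch(scope,
    "all" = rep(TRUE, nrow(atoms)),
    "heavy" = !is_hydrogen(atoms),
    "backbone" = atoms$name %in% BACKBONE_NAMES,
    "sidechain-heavy" = !is_hydrogen(atoms) &
      !(atoms$name %in% BACKBONE_NAMES),
    stop("unknown atom scope: '", scope, "'", call. = FALSE))
}

new_selection <- function(indices, expression = "") {
  indices <- as.integer(sort(unique(indices)))
  structure(list(indices = indices, expression = expression),
            class = "Selection")
}

#' @export
print.Selection <- function(x, ...) {
  cat("Selection:", length(x$indices), "atoms",
      if (nzchar(x$expression)) paste0("<", x$expression, ">"), "\n")
  invisible(x)
}

#' @export
length.Selection <- function(x) length(x$indices)

## Programmatic selection used internally by the analyses.
select_atoms <- function(top, chain = NULL, resid = NULL, name = NULL,
                         scope = NULL, resname = NULL) {
  at <- top$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(name)) keep <- keep & at$name %in% name
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!is.null(scope)) keep <- keep & atom_scope_mask(at, scope)
  new_selection(which(keep))
}

#' Resolve a selection expression against a topology
#'
#' The selector grammar combines terms with implicit AND inside a group and
#' the keyword `or` between groups. Terms:
#' \describe{
#'   \item{`subunit:GIRK1`}{atoms on chains assigned to that subunit type}
#'   \item{`role:PIP2-lysines`}{atoms whose (subunit, resid) is listed under
#'     that role in the role map}
#'   \item{`chain:A`}{chain id}
#'   \item{`name:NZ` / `name:O11,O12`}{atom name(s)}
#'   \item{`resname:PIP`}{residue name}
#'   \item{`resid 90-95`, `resid:90-95`, `resid:90`}{canonical residue
#'     range (an empty range such as `90-89` selects nothing)}
#'   \item{`scope:sidechain-heavy`}{atom scope: `all`, `heavy`, `backbone`
#'     (N, CA, C, O) or `sidechain-heavy` (heavy atoms excluding the
#'     backbone)}
#' }
#'
#' @param top a [Topology].
#' @param assignment a [subunit_assignment()] (required for `subunit:` and
#'   `role:` terms).
#' @param roles a `ResidueRoleMap` (required for `role:` terms).
#' @param expression selector text.
#' @return A `Selection` (ordered atom indices; may be empty).
#' @export
resolve_selection <- function(top, assignment = NULL, roles = NULL,
                              expression = "") {
  tokens <- strsplit(trimws(expression), "\\s+")[[1]]
  tokens <- tokens[tokens != "" & tolower(tokens) != "and"]
  ## re-join the two-token `resid 90-95` form
  i <- 1
  merged <- character()
  while (i <= length(tokens)) {
    if (tolower(tokens[i]) == "resid" && i < length(tokens)) {
      merged <- c(merged, paste0("resid:", tokens[i + 1]))
      i <- i + 2
    } else {
      merged <- c(merged, tokens[i])
      i <- i + 1
    }
  }
  groups <- split(merged, cumsum(tolower(merged) == "or"))
  at <- top$atoms
  overall <- rep(FALSE, nrow(at))
  for (grp in groups) {
    grp <- grp[tolower(grp) != "or"]
    mask <- rep(TRUE, nrow(at))
    for (term in grp) mask <- mask & term_mask(term, at, assignment, roles)
    overall <- overall | mask
  }
  if (!length(merged)) overall <- rep(TRUE, nrow(at))
  new_selection(which(overall), expression)
}

term_mask <- function(term, at, assignment, roles) {
  m <- regmatches(term, regexec("^([A-Za-z]+):(.*)$", term))[[1]]
  if (length(m) != 3) {
    stop("selection syntax error in term '", term,
         "': expected key:value", call. = FALSE)
  }
  key <- tolower(m[2]); val <- m[3]
  switch(key,
    chain = at$chain %in% strsplit(val, ",")[[1]],
    name = at$name %in% strsplit(val, ",")[[1]],
    resname = at$resname %in% strsplit(val, ",")[[1]],
    scope = atom_scope_mask(at, val),
    resid = {
      if (grepl("-", val)) {
        ab <- as.integer(strsplit(val, "-")[[1]])
        if (any(is.na(ab)) || length(ab) != 2) {
          stop("selection syntax error in term '", term, "'", call. = FALSE)
        }
        if (ab[1] > ab[2]) rep(FALSE, nrow(at)) else
          at$resid >= ab[1] & at$resid <= ab[2]
      } else {
        at$resid == as.integer(val)
      }
    },
    subunit = {
      if (is.null(assignment)) {
        stop("'subunit:' term requires a subunit assignment", call. = FALSE)
      }
      if (!val %in% assignment) {
        stop("no chain assigned to subunit '", val, "'", call. = FALSE)
      }
      at$chain %in% names(assignment)[assignment == val]
    },
    role = {
      if (is.null(roles) || is.null(assignment)) {
        stop("'role:' term requires a role map and assignment",
             call. = FALSE)
      }
      entry <- roles[[val]]
      if (is.null(entry)) stop("unknown role: '", val, "'", call. = FALSE)
      mask <- rep(FALSE, nrow(at))
      for (su in names(entry)) {
        ch <- names(assignment)[assignment == su]
        if (length(ch)) {
          mask <- mask | (at$chain %in% ch & at$resid %in% entry[[su]])
        }
      }
      mask
    },
    stop("selection syntax error: unknown key '", key, "' in term '",
         term, "'", call. = FALSE))
}

sel_indices <- function(sel) {
  if (inherits(sel, "Selection")) sel$indices else as.integer(sel)
}
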