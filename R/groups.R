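#' Group (pathway) structure over predictors
#'
#' Describes how predictors are organised into `G` named groups, e.g.
#' biological pathways.  Groups may overlap: a predictor can belong to any
#' number of groups.  Overlap is resolved at fitting time by replicating the
#' predictor once per group it appears in ([expand_overlap]), following the
#' overlap-group-lasso convention.
#'
#' @param groups A list of integer vectors of predictor (column) indices, one
#'   vector per group; or a list of character vectors of predictor names,
#'   resolved against `predictor_names`.  Names of the list become group
#'   names (defaults `g1`, `g2`, ... otherwise).
#' @param m Number of predictors in the matrix the structure refers to.
#' @param predictor_names Optional character vector of predictor names used
#'   to resolve character group members.
#' @param catch_all If `TRUE` (default), predictors belonging to no group are
#'   pooled into one extra group named `".rest"`, mirroring the common
#'   treatment of genes mapped to no pathway.  If `FALSE`, such predictors
#'   are excluded from the model.
#'
#' @return An object of class `"group_structure"`: list with `groups` (named
#'   list of integer index vectors), `m`, and `G` (number of groups).
#' @examples
#' gs <- group_structure(list(a = 1:3, b = 3:4), m = 6)
#' gs$G          # 3: the two groups plus the ".rest" catch-all {5, 6}
#' @export
group_structure <- function(groups, m, predictor_names = NULL,
                            catch_all = TRUE) {
  if (!is.list(groups) || length(groups) == 0)
    stop("'groups' must be a non-empty list")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  nm[nm == ""] <- paste0("g", which(nm == ""))
  if (anyDuplicated(nm)) stop("duplicate group names")
  groups <- lapply(groups, function(g) {
    if (is.character(g)) {
      if (is.null(predictor_names))
        stop("character group members require 'predictor_names'")
      i <- match(g, predictor_names)
      if (anyNA(i)) {
        message(sum(is.na(i)), " group member(s) not found among predictors; dropped")
        i <- i[!is.na(i)]
      }
      i
    } else as.integer(g)
  })
  keep <- lengths(groups) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " group(s) with no matched members")
    groups <- groups[keep]
    nm <- nm[keep]
  }
  if (length(groups) == 0) stop("no non-empty groups")
  all_idx <- unlist(groups)
  if (any(all_idx < 1L | all_idx > m)) stop("group index out of range 1..m")
  if (any(vapply(groups, anyDuplicated, 1L) > 0))
    stop("a predictor appears twice within one group")
  if (catch_all) {
    rest <- setdiff(seq_len(m), all_idx)
    if (length(rest) > 0) {
      groups <- c(groups, list(rest))
      nm <- c(nm, ".rest")
    }
  }
  names(groups) <- nm
  structure(list(groups = groups, m = as.integer(m), G = length(groups)),
            class = "group_structure")
}

#' @export
print.group_structure <- function(x, ...) {
  cat(sprintf("Group structure: %d groups over %d predictors (%d expanded columns)\n",
              x$G, x$m, sum(lengths(x$groups))))
  invisible(x)
}

# single catch-all structure used when no grouping is supplied
.default_groups <- function(m) {
  group_structure(list(all = seq_len(m)), m = m, catch_all = FALSE)
}

#' Expand a predictor matrix over overlapping groups
#'
#' Replicates every predictor once per group it belongs to, producing an
#' expanded design on which the groups are disjoint.  The expanded column
#' count is the sum of group sizes `J = sum(J_g)`; for non-overlapping
#' structures the result is a column permutation of the input.
#'
#' @param x Predictor matrix (samples x predictors).
#' @param gs A [group_structure] over `ncol(x)` predictors.
#' @return An object of class `"expanded_design"`: list with `x` (expanded
#'   matrix), `orig` (original column index per expanded column), `group`
#'   (group index per expanded column), `group_sizes` (`J_g`), and `J`.
#' @export
expand_overlap <- function(x, gs) {
  if (!inherits(gs, "group_structure")) stop("'gs' must be a group_structure")
  if (ncol(x) != gs$m) stop("ncol(x) != gs$m")
  orig <- unlist(gs$groups, use.names = FALSE)
  grp <- rep(seq_len(gs$G), lengths(gs$groups))
  xe <- x[, orig, drop = FALSE]
  colnames(xe) <- if (!is.null(colnames(x))) {
    make.unique(colnames(x)[orig])
  } else paste0("x", orig, ".", grp)
  structure(list(x = xe, orig = orig, group = grp,
                 group_sizes = lengths(gs$groups), J = length(orig),
                 group_names = names(gs$groups), m = gs$m),
            class = "expanded_design")
}

#' Collapse expanded coefficients back to the original predictors
#'
#' Sums the coefficients of all replicates of each original predictor
#' (overlap-group-lasso convention), so the linear predictor computed from
#' the collapsed coefficients on the original matrix equals that from the
#' expanded coefficients on the expanded design exactly.
#'
#' @param beta Numeric vector of coefficients on expanded columns.
#' @param ed An [expand_overlap] result (or any list with `orig` and `m`).
#' @return Numeric vector of length `ed$m`, one coefficient per original
#'   predictor (zero for predictors outside every group).
#' @export
collapse_coefficients <- function(beta, ed) {
  if (length(beta) != length(ed$orig)) stop("length(beta) != number of expanded columns")
  out <- numeric(ed$m)
  agg <- rowsum(beta, ed$orig)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Read group membership from a GMT file
#'
#' Parses the standard tab-separated GMT gene-set format: one group per line
#' as `name<TAB>description<TAB>member1<TAB>member2...`.  Members are
#' resolved against the predictor names when supplied; unmatched members are
#' dropped with a message, groups with no matched member are dropped with a
#' warning, and duplicate group names are an error.
#'
#' @param path Path to the GMT file.
#' @param predictor_names Optional character vector (e.g. the predictor
#'   matrix header) against which members are resolved.  If omitted, the raw
#'   member names are kept and resolution happens later.
#' @param m Number of predictors; required when `predictor_names` is absent.
#' @param catch_all Passed to [group_structure].
#' @return A [group_structure] when members can be resolved; otherwise a
#'   named list of character member vectors.
#' @export
read_gmt <- function(path, predictor_names = NULL, m = length(predictor_names),
                     catch_all = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ", which(bad)[1L])
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate group names in GMT file")
  members <- lapply(parts, function(p) p[-(1:2)])
  names(members) <- nm
  if (is.null(predictor_names)) return(members)
  group_structure(members, m = m, predictor_names = predictor_names,
                  catch_all = catch_all)
}

#' Write a group structure to a GMT file
#'
#' @param gs A [group_structure].
#' @param path Output path.
#' @param predictor_names Names used for the members (defaults `x1`, `x2`, ...).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path, predictor_names = paste0("x", seq_len(gs$m))) {
  lines <- vapply(seq_len(gs$G), function(g) {
    paste(c(names(gs$groups)[g], "na", predictor_names[gs$groups[[g]]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
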