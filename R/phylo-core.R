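#' @useDynLib vertbrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef resid var sd quantile optimize pchisq pt qnorm
#'   rnorm runif model.matrix setNames acf complete.cases
#' @importFrom utils head
NULL

# ---- Newick I/O -------------------------------------------------------------

#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. Square-bracket comments
#' are stripped before parsing; quoted and internal-node labels are accepted.
#' Unlike the raw reader, a malformed string raises an error that names the
#' character offset of the first unbalanced bracket, and a tree with missing
#' branch lengths is rejected rather than silently given defaults.
#'
#' @param text A Newick string (single tree, terminated by `;`).
#' @return An object of class `phylo` (see [ape::read.tree()]).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- strip_newick_comments(text)
  check_newick_balanced(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick string (reader failed after bracket check)")
  }
  if (is.null(tr$edge.length)) {
    stop("Newick string has no branch lengths; lengths are required")
  }
  if (anyNA(tr$edge.length)) {
    stop("Newick string has ", sum(is.na(tr$edge.length)),
         " edge(s) with missing branch lengths; lengths are required")
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed")
  }
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  tr
}

# remove [...] comments (non-nested, per common Newick practice)
strip_newick_comments <- function(text) {
  gsub("\\[[^]]*\\]", "", text)
}

check_newick_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick string: unmatched ')' at character offset ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed Newick string: ", depth,
         " unclosed '(' (first at character offset ",
         which(chars == "(")[1], ")")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed Newick string: missing terminating ';' at character offset ",
         nchar(text) + 1L)
  }
  invisible(TRUE)
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths. The default of 17
#'   round-trips IEEE doubles exactly, so `parse_newick(write_newick(x))`
#'   preserves all patristic distances bit-for-bit.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 17) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

# ---- Tree geometry ----------------------------------------------------------

#' Root-to-tip depths and tree height
#'
#' @param tree A `phylo` object with branch lengths.
#' @return `tip_depths()`: named numeric vector of root-to-tip path lengths.
#'   `tree_height()`: the maximum root-to-tip path length, which for an
#'   ultrametric (time-calibrated) tree is its root age.
#' @export
tip_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nd <- ape::node.depth.edgelength(tree)
  setNames(nd[seq_len(ape::Ntip(tree))], tree$tip.label)
}

#' @rdname tip_depths
#' @export
tree_height <- function(tree) {
  max(tip_depths(tree))
}

#' Check that a tree is ultrametric
#'
#' All root-to-tip distances must agree with the maximum depth within a
#' relative tolerance (default 1e-6, loose enough for the rounded branch
#' lengths of published chronograms).
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on root-to-tip depth.
#' @param strict If `TRUE` (default) an error is raised on failure; otherwise
#'   `FALSE` is returned.
#' @return `TRUE` invisibly (or `FALSE` when `strict = FALSE` and the check
#'   fails).
#' @export
validate_ultrametric <- function(tree, tol = 1e-6, strict = TRUE) {
  d <- tip_depths(tree)
  h <- max(d)
  ok <- h == 0 || all(abs(d - h) <= tol * h)
  if (!ok && strict) {
    worst <- which.max(abs(d - h))
    stop("tree is not ultrametric: tip '", names(d)[worst], "' has depth ",
         format(d[worst]), " vs root age ", format(h),
         " (relative tolerance ", tol, ")")
  }
  invisible(ok)
}

# ---- Supertree grafting -----------------------------------------------------

#' Read or construct a grafting schedule
#'
#' A grafting schedule is an ordered list of steps, each joining the clade
#' containing taxon set `a` with the clade containing `b` at a last-common-
#' ancestor (LCA) age in Myr. Schedules are stored as JSON arrays of
#' `{"a": ..., "b": ..., "age": ...}` objects.
#'
#' @param path Path to a schedule JSON file.
#' @return A data frame with columns `a`, `b`, `age` and class
#'   `graft_schedule`.
#' @export
read_graft_schedule <- function(path) {
  x <- jsonlite::fromJSON(path)
  as_graft_schedule(x)
}

#' @rdname read_graft_schedule
#' @param x A data frame (or coercible) with columns `a`, `b`, `age`.
#' @export
as_graft_schedule <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot(all(c("a", "b", "age") %in% names(x)))
  x$age <- as.numeric(x$age)
  if (any(!is.finite(x$age)) || any(x$age <= 0)) {
    stop("schedule ages must be positive finite numbers")
  }
  class(x) <- c("graft_schedule", "data.frame")
  x
}

#' The default vertebrate grafting schedule
#'
#' Eight steps joining the class-level chronograms into a single dated
#' vertebrate supertree: Aves + Crocodylia at 244.8 Myr, then Testudines
#' (261.4), Lepidosauria (279.9), Mammalia (318.9), Amphibia (351.7),
#' Actinopterygii (429.0), Chondrichthyes (462.4) and finally Agnatha at
#' 563.4 Myr. Shipped as a packaged JSON file so that calibrations can be
#' replaced without touching code.
#'
#' @return A `graft_schedule` data frame with eight rows.
#' @export
default_graft_schedule <- function() {
  read_graft_schedule(system.file("extdata", "graft_schedule.json",
                                  package = "vertbrain", mustWork = TRUE))
}

#' Graft ultrametric subtrees into a dated supertree
#'
#' Each schedule step locates the running components containing clades `a`
#' and `b` and joins them under a new root at the step's LCA age, with stem
#' branches `age - component_height`. Within-subtree patristic distances are
#' preserved exactly; the MRCA age of any cross-clade tip pair at step *k*
#' equals that step's age, and the final root age is the last (oldest)
#' step's age.
#'
#' @param subtrees Named list of ultrametric `phylo` objects; names are the
#'   clade ids referenced by the schedule.
#' @param schedule A `graft_schedule` (see [read_graft_schedule()]).
#' @param tol Ultrametricity tolerance passed to [validate_ultrametric()];
#'   also used to forgive numerically tiny negative stems.
#' @return An ultrametric `phylo` whose tips carry a `clade` attribute
#'   (named character vector mapping tip label to originating clade id).
#' @export
graft_supertree <- function(subtrees, schedule, tol = 1e-6) {
  stopifnot(is.list(subtrees), length(subtrees) >= 1)
  if (is.null(names(subtrees)) || any(names(subtrees) == "")) {
    stop("subtrees must be a named list of clade ids")
  }
  schedule <- as_graft_schedule(schedule)
  all_tips <- unlist(lapply(subtrees, function(t) t$tip.label))
  if (anyDuplicated(all_tips)) {
    stop("tip labels shared between subtrees: ",
         paste(unique(all_tips[duplicated(all_tips)]), collapse = ", "))
  }
  for (nm in names(subtrees)) validate_ultrametric(subtrees[[nm]], tol = tol)

  # forest components: each holds a newick fragment (no trailing ';'),
  # its height, and the clade ids it covers
  comps <- lapply(names(subtrees), function(nm) {
    tr <- subtrees[[nm]]
    list(frag = newick_fragment(tr), height = tree_height(tr), clades = nm)
  })

  find_comp <- function(clade) {
    hit <- which(vapply(comps, function(cp) clade %in% cp$clades, logical(1)))
    if (length(hit) != 1L) stop("unknown clade id in schedule: '", clade, "'")
    hit
  }

  joined_as_new <- character(0)
  for (k in seq_len(nrow(schedule))) {
    a <- schedule$a[k]; b <- schedule$b[k]; age <- schedule$age[k]
    ia <- find_comp(a); ib <- find_comp(b)
    if (ia == ib) {
      stop("schedule step ", k, " joins clades '", a, "' and '", b,
           "' that are already in the same component")
    }
    for (cl in c(a, b)) {
      if (cl %in% joined_as_new) {
        stop("clade id '", cl, "' referenced as a joiner more than once")
      }
    }
    joined_as_new <- c(joined_as_new, b)
    stem_a <- age - comps[[ia]]$height
    stem_b <- age - comps[[ib]]$height
    if (stem_a < -tol * age || stem_b < -tol * age) {
      stop("schedule step ", k, " (age ", age, " Myr) is younger than a ",
           "joined subtree's root age (", format(comps[[ia]]$height), ", ",
           format(comps[[ib]]$height), "): negative stem branch")
    }
    stem_a <- max(stem_a, 0); stem_b <- max(stem_b, 0)
    merged <- list(
      frag = paste0("(", comps[[ia]]$frag, ":", format_bl(stem_a), ",",
                    comps[[ib]]$frag, ":", format_bl(stem_b), ")"),
      height = age,
      clades = c(comps[[ia]]$clades, comps[[ib]]$clades)
    )
    comps <- c(comps[-c(ia, ib)], list(merged))
  }
  if (length(comps) != 1L) {
    stop("schedule leaves ", length(comps),
         " disconnected components; expected one supertree")
  }
  out <- parse_newick(paste0(comps[[1]]$frag, ";"))
  validate_ultrametric(out, tol = tol)
  clade_of <- unlist(lapply(names(subtrees), function(nm) {
    setNames(rep(nm, ape::Ntip(subtrees[[nm]])), subtrees[[nm]]$tip.label)
  }))
  attr(out, "clade") <- clade_of[out$tip.label]
  out
}

# Newick fragment of a tree without the trailing ';'; single-tip trees
# collapse to "label:depth" so no degree-2 node is created when grafting.
newick_fragment <- function(tree) {
  if (ape::Ntip(tree) == 1L) {
    return(paste0(tree$tip.label, ":", format_bl(tree_height(tree))))
  }
  sub(";$", "", write_newick(tree))
}

format_bl <- function(x) sprintf("%.17g", x)

# ---- Phylogenetic covariance ------------------------------------------------

#' Shared-path phylogenetic covariance matrix
#'
#' Builds the standard Brownian-motion covariance: entry (i, j) is the depth
#' (shared path length from the root, in Myr) of the most recent common
#' ancestor of tips i and j; diagonal entries are root-to-tip depths. The
#' result carries a Pagel's-lambda multiplier, initialized to 1.
#'
#' @param tree An ultrametric `phylo`.
#' @param taxa_order Character vector fixing the row/column order; defaults
#'   to the tree's tip order.
#' @return An object of class `phylo_cov`: list with `matrix` (dimnamed),
#'   `taxa`, `lambda`.
#' @export
shared_path_covariance <- function(tree, taxa_order = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(taxa_order)) taxa_order <- tree$tip.label
  missing <- setdiff(taxa_order, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  V <- ape::vcv(tree)
  V <- V[taxa_order, taxa_order, drop = FALSE]
  structure(list(matrix = V, taxa = taxa_order, lambda = 1),
            class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat("Phylogenetic covariance over", length(x$taxa), "taxa; lambda =",
      x$lambda, "\n")
  cat("root-to-tip depth (diag):", format(mean(diag(x$matrix))), "\n")
  invisible(x)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies all off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: lambda = 1 is the Brownian expectation, lambda = 0 a star
#' phylogeny.
#'
#' @param cov A `phylo_cov` or a plain symmetric matrix.
#' @param lambda Real in \[0, 1\].
#' @return Same type as `cov`, with the transform applied (and the `lambda`
#'   field updated for `phylo_cov` input).
#' @export
lambda_transform <- function(cov, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]")
  }
  if (inherits(cov, "phylo_cov")) {
    M <- cov$matrix
    d <- diag(M)
    M <- M * lambda
    diag(M) <- d
    cov$matrix <- M
    cov$lambda <- lambda
    cov$eigen <- NULL  # transform invalidates any cached decomposition
    return(cov)
  }
  M <- as.matrix(cov)
  d <- diag(M)
  M <- M * lambda
  diag(M) <- d
  M
}

# coerce phylo_cov / matrix input to a plain matrix
cov_matrix <- function(cov) {
  if (inherits(cov, "phylo_cov")) cov$matrix else as.matrix(cov)
}

#' Write a covariance matrix as delimited text
#'
#' @param cov A `phylo_cov` or matrix.
#' @param path Output file; tab-delimited with a header row of taxa.
#' @export
write_covariance <- function(cov, path) {
  M <- cov_matrix(cov)
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
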