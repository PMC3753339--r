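#' @keywords internal
"_PACKAGE"

# The three abstract gene classes, in the order used throughout:
# (division, apoptosis, segregation), matching the (d, a, s) genotype notation.
GENE_CLASSES <- c("division", "apoptosis", "segregation")

#' Gene-linkage distributions
#'
#' A gene distribution assigns the three abstract gene classes -- cell-division
#' regulators (proto-oncogene abstraction), apoptosis regulators (tumour
#' suppressor abstraction) and chromosome-segregation regulators (genetic
#' stability abstraction) -- to chromosome types. Genes sharing a chromosome
#' are "linked": they are gained and lost together at mis-segregation.
#'
#' The four named layouts are:
#' \describe{
#'   \item{A}{division + apoptosis linked on one chromosome; segregation alone.}
#'   \item{B}{division + segregation linked; apoptosis alone.}
#'   \item{C}{apoptosis + segregation linked; division alone.}
#'   \item{unlinked}{three chromosomes, one gene class each (control).}
#' }
#'
#' A custom layout may be given as a list of per-type gene-content vectors,
#' e.g. `list(chr1 = c(division = 1, apoptosis = 1), chr2 = c(segregation = 1))`.
#' Each gene class must appear on exactly one chromosome type so that the
#' diploid starting genome always has genotype state (2, 2, 2).
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"unlinked"`, or a list describing
#'   a custom layout (see Details).
#' @return an object of class `gene_distribution`: a list with elements
#'   `name` and `content`, an integer matrix (chromosome types x gene classes)
#'   of gene copies carried per chromosome.
#' @examples
#' gene_distribution("A")
#' gene_distribution("unlinked")
#' @export
gene_distribution <- function(name = c("A", "B", "C", "unlinked")) {
  if (is.list(name)) {
    return(custom_gene_distribution(name))
  }
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("A", "B", "C", "unlinked")) {
    stop("unknown gene distribution: must be one of \"A\", \"B\", \"C\", ",
         "\"unlinked\", or a custom layout list", call. = FALSE)
  }
  content <- switch(name,
    A = rbind(chr1 = c(1L, 1L, 0L), chr2 = c(0L, 0L, 1L)),
    B = rbind(chr1 = c(1L, 0L, 1L), chr2 = c(0L, 1L, 0L)),
    C = rbind(chr1 = c(0L, 1L, 1L), chr2 = c(1L, 0L, 0L)),
    unlinked = rbind(chr1 = c(1L, 0L, 0L), chr2 = c(0L, 1L, 0L),
                     chr3 = c(0L, 0L, 1L))
  )
  colnames(content) <- GENE_CLASSES
  new_gene_distribution(name, content)
}

new_gene_distribution <- function(name, content) {
  structure(list(name = name, content = content), class = "gene_distribution")
}

custom_gene_distribution <- function(layout) {
  if (length(layout) < 1L) {
    stop("custom gene distribution needs at least one chromosome type",
         call. = FALSE)
  }
  ids <- names(layout)
  if (is.null(ids) || any(ids == "")) {
    ids <- paste0("chr", seq_along(layout))
  }
  content <- matrix(0L, nrow = length(layout), ncol = 3L,
                    dimnames = list(ids, GENE_CLASSES))
  for (i in seq_along(layout)) {
    g <- layout[[i]]
    bad <- setdiff(names(g), GENE_CLASSES)
    if (length(bad)) {
      stop("unknown gene class in custom layout: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    content[i, names(g)] <- as.integer(g)
  }
  if (any(content < 0L)) {
    stop("gene content must be non-negative", call. = FALSE)
  }
  if (any(rowSums(content) == 0L)) {
    stop("every chromosome type must carry at least one gene", call. = FALSE)
  }
  carriers <- colSums(content > 0L)
  if (any(carriers != 1L)) {
    stop("each gene class must appear on exactly one chromosome type ",
         "(violated for: ",
         paste(GENE_CLASSES[carriers != 1L], collapse = ", "), ")",
         call. = FALSE)
  }
  new_gene_distribution("custom", content)
}

#' @export
print.gene_distribution <- function(x, ...) {
  cat("Gene distribution", x$name, "\n")
  print(x$content)
  invisible(x)
}

#' Diploid starting genome
#'
#' Every simulation starts from a diploid genome: two copies of each
#' chromosome type of the distribution, i.e. genotype state (2, 2, 2).
#'
#' @param distribution a [gene_distribution()] or the name of one.
#' @return an object of class `genome`: an integer vector of copy counts
#'   named by chromosome type, carrying the distribution as an attribute.
#' @examples
#' g <- make_initial_genome("A")
#' genotype_state(g)  # (2, 2, 2)
#' @export
make_initial_genome <- function(distribution) {
  dist <- as_gene_distribution(distribution)
  counts <- rep(2L, nrow(dist$content))
  names(counts) <- rownames(dist$content)
  new_genome(counts, dist)
}

as_gene_distribution <- function(x) {
  if (inherits(x, "gene_distribution")) x else gene_distribution(x)
}

new_genome <- function(counts, dist) {
  structure(counts, distribution = dist, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  dist <- attr(x, "distribution")
  s <- genotype_state(x)
  cat("Genome (distribution ", dist$name, "): ",
      paste0(names(x), "=", as.integer(x), collapse = ", "),
      "; state (", paste(s, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Genotype state of a genome
#'
#' The genotype state is the triple (n_div, n_apop, n_seg) of total gene
#' copies carried by a genome -- the unit of clone identity in the model,
#' written (Number of Division Genes, Number of Death Genes, Number of
#' Segregation Genes).
#'
#' @param genome a `genome` object.
#' @return a named integer vector `c(division=, apoptosis=, segregation=)`.
#' @examples
#' genotype_state(make_initial_genome("B"))
#' @export
genotype_state <- function(genome) {
  dist <- attr(genome, "distribution")
  if (is.null(dist)) stop("not a genome: missing distribution", call. = FALSE)
  s <- as.integer(unclass(genome)) %*% dist$content
  stats::setNames(as.integer(s), GENE_CLASSES)
}

# chromosome-copy picker shared by segregate() and the simulation engine.
# counts: integer vector of copies per type.  sampling "copy": each physical
# copy equally likely (types weighted by copy number); "type": each type with
# >= 1 copy equally likely.
pick_chromosome <- function(counts, sampling = "copy") {
  present <- which(counts > 0L)
  if (!length(present)) {
    stop("cannot mis-segregate a genome with zero chromosomes", call. = FALSE)
  }
  if (sampling == "type") {
    if (length(present) == 1L) return(present)
    return(sample(present, 1L))
  }
  if (length(present) == 1L) return(present)
  sample.int(length(counts), 1L, prob = counts)
}

#' Segregate a genome into two daughter genomes
#'
#' A faithful division duplicates the genome so both daughters equal the
#' mother. A mis-segregation picks one chromosome copy at random and
#' distributes it asymmetrically: one daughter gains a copy of that type, the
#' other loses one. Copy number is always conserved: daughter1 + daughter2 =
#' 2 x mother, elementwise.
#'
#' Which daughter gains is decided by a fair coin; a daughter left with zero
#' copies of every chromosome type is nonviable and the corresponding list
#' entry is `NULL`.
#'
#' @param genome a `genome` object with at least one chromosome copy when
#'   `missegregate` is `TRUE`.
#' @param missegregate logical; if `FALSE` both daughters copy the mother.
#' @param sampling `"copy"` (default: uniform over chromosome copies) or
#'   `"type"` (uniform over chromosome types present).
#' @return list of two `genome` objects (a nonviable daughter is `NULL`).
#' @examples
#' set.seed(1)
#' segregate(make_initial_genome("A"), missegregate = TRUE)
#' @export
segregate <- function(genome, missegregate = FALSE,
                      sampling = c("copy", "type")) {
  sampling <- match.arg(sampling)
  dist <- attr(genome, "distribution")
  counts <- as.integer(unclass(genome))
  names(counts) <- names(unclass(genome))
  if (!missegregate) {
    d <- new_genome(counts, dist)
    return(list(d, d))
  }
  k <- pick_chromosome(counts, sampling)
  gain <- counts; gain[k] <- gain[k] + 1L
  lose <- counts; lose[k] <- lose[k] - 1L
  daughters <- if (stats::runif(1L) < 0.5) list(gain, lose) else list(lose, gain)
  lapply(daughters, function(d) {
    if (all(d == 0L)) NULL else new_genome(d, dist)
  })
}

#' Genotype colour key
#'
#' Maps a genotype state into RGB space by normalising against the maximum
#' observed state: red intensity for division genes, green for apoptosis
#' (death) genes, blue for segregation genes. (0,0,0) is black, the diploid
#' (2,2,2) under max (5,5,5) dark grey, and the maximum state white.
#'
#' @param state genotype state (length-3 numeric, order division, apoptosis,
#'   segregation).
#' @param max_state componentwise maximum observed state; components that are
#'   zero in `max_state` map to 0.
#' @return numeric triplet in \[0, 1\]^3 named r, g, b.
#' @examples
#' rgb_color(c(2, 2, 2), c(5, 5, 5))
#' @export
rgb_color <- function(state, max_state) {
  state <- as.numeric(state)
  max_state <- as.numeric(max_state)
  stopifnot(length(state) == 3L, length(max_state) == 3L)
  out <- ifelse(max_state > 0, state / max_state, 0)
  out <- pmin(pmax(out, 0), 1)
  stats::setNames(out, c("r", "g", "b"))
}
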