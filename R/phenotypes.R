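#' Egg phenotype encoding
#'
#' The model tracks four egg phenotypes, the cross of a background color
#' (white or blue) with a spottiness state (immaculate or spotted).  The
#' index order is fixed throughout the package:
#' 1 = immaculate white, 2 = immaculate blue, 3 = spotted white,
#' 4 = spotted blue.  Color is the fast-varying trait, spottiness the
#' slow one, so two-trait matrices factor as Kronecker products
#' (spottiness x color) under this order.
#'
#' @return A data frame with one row per phenotype and columns
#'   `index`, `color` (`"white"`/`"blue"`) and
#'   `spottiness` (`"immaculate"`/`"spotted"`).
#' @examples
#' egg_phenotypes()
#' @export
egg_phenotypes <- function() {
  data.frame(
    index = 1:4,
    color = c("white", "blue", "white", "blue"),
    spottiness = c("immaculate", "immaculate", "spotted", "spotted"),
    stringsAsFactors = FALSE
  )
}

#' Trait of a phenotype index
#'
#' Total functions from the phenotype index 1..4 to its two traits.
#'
#' @param i integer vector of phenotype indices in `{1, 2, 3, 4}`.
#' @return `phenotype_color()` returns `"white"` or `"blue"`;
#'   `phenotype_spottiness()` returns `"immaculate"` or `"spotted"`.
#' @examples
#' phenotype_color(1:4)
#' phenotype_spottiness(1:4)
#' @export
phenotype_color <- function(i) {
  stopifnot(all(i %in% 1:4))
  c("white", "blue", "white", "blue")[i]
}

#' @rdname phenotype_color
#' @export
phenotype_spottiness <- function(i) {
  stopifnot(all(i %in% 1:4))
  c("immaculate", "immaculate", "spotted", "spotted")[i]
}

#' Phenotype label permutations
#'
#' The model is symmetric under relabeling white with blue (which swaps
#' indices 1 and 2, and 3 and 4) and under relabeling immaculate with
#' spotted (swapping 1 with 3, and 2 with 4).  These helpers return the
#' corresponding index permutations; applying one to both population
#' vectors commutes exactly with the one-generation update.
#'
#' @return An integer vector `perm` of length 4 such that entry `i` of
#'   the relabeled frequency vector is entry `perm[i]` of the original.
#' @examples
#' swap_color()       # c(2, 1, 4, 3)
#' swap_spottiness()  # c(3, 4, 1, 2)
#' @export
swap_color <- function() c(2L, 1L, 4L, 3L)

#' @rdname swap_color
#' @export
swap_spottiness <- function() c(3L, 4L, 1L, 2L)
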