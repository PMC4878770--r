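#' The three-generation pedigree structure
#'
#' Eleven individuals: four unrelated grandparents (P generation), two F1
#' parents, and five F2 offspring. In this ZW system the heterogametic sex is
#' the female; the default pedigree carries four females (both grandmothers,
#' the F1 mother and one F2 offspring), matching a typical sequencing design.
#'
#' @return data.frame with columns \code{id}, \code{sex} ("F"/"M"),
#'   \code{generation} ("P", "F1", "F2"), \code{father}, \code{mother}
#'   (\code{NA} for founders).
#' @examples
#' flycatcherPedigree()
#' @export
flycatcherPedigree <- function() {
  data.frame(
    id = c("pgf", "pgm", "mgf", "mgm", "father", "mother",
           paste0("off", 1:5)),
    sex = c("M", "F", "M", "F", "M", "F", "M", "M", "M", "M", "F"),
    generation = c(rep("P", 4), rep("F1", 2), rep("F2", 5)),
    father = c(NA, NA, NA, NA, "pgf", "mgf", rep("father", 5)),
    mother = c(NA, NA, NA, NA, "pgm", "mgm", rep("mother", 5)),
    stringsAsFactors = FALSE
  )
}

# Role lookups used throughout: the "paternal" side is the F1 father's
# transmission (grandparents pgf/pgm, partner = mother); the "maternal" side
# is the F1 mother's (grandparents mgf/mgm, partner = father).
sideRoles <- function(pedigree, side) {
  side <- match.arg(side, c("paternal", "maternal"))
  f2 <- pedigree$id[pedigree$generation == "F2"]
  f1 <- pedigree$id[pedigree$generation == "F1"]
  fa <- f1[pedigree$sex[match(f1, pedigree$id)] == "M"]
  mo <- f1[pedigree$sex[match(f1, pedigree$id)] == "F"]
  if (side == "paternal") {
    list(f1 = fa, partner = mo,
         gf = pedigree$father[match(fa, pedigree$id)],
         gm = pedigree$mother[match(fa, pedigree$id)],
         offspring = f2, side = "paternal")
  } else {
    list(f1 = mo, partner = fa,
         gf = pedigree$father[match(mo, pedigree$id)],
         gm = pedigree$mother[match(mo, pedigree$id)],
         offspring = f2, side = "maternal")
  }
}

checkPedigree <- function(pedigree) {
  need <- c("id", "sex", "generation", "father", "mother")
  if (!all(need %in% names(pedigree)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  if (sum(pedigree$generation == "F1") != 2)
    stop("pedigree must contain exactly two F1 individuals")
  if (!any(pedigree$generation == "F2"))
    stop("pedigree must contain F2 offspring")
  invisible(pedigree)
}
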