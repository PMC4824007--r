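# Shared, lazily built fixtures. Everything is generated in code at test
# time; the expensive mini survey is memoised across test files.

.testCache <- new.env(parent = emptyenv())

miniTaxonomy <- function() {
  if (is.null(.testCache$tax))
    .testCache$tax <- generateTaxonomy(
      nPerClade = 2L,
      cladeSeries = c("LECA", "Opisthokonta", "Metazoa"),
      outgroups = "Excavata")
  .testCache$tax
}

miniSpecs <- function() {
  arch <- function(...) {
    x <- c(...)
    data.frame(domain = names(x), length = unname(x))
  }
  list(
    FAMA = familySpec("FAMA", arch(DA = 50L, DB = 45L), "LECA"),
    FAMB = familySpec("FAMB", arch(DC = 50L), "Metazoa",
      events = list(list(type = "motif_plant", clade = "Metazoa",
                         motif = "NPF", region = "C_tail"))))
}

miniFixture <- function() {
  if (is.null(.testCache$fx))
    .testCache$fx <- generateSurveyFixture(
      specs = miniSpecs(), tax = miniTaxonomy(), nDecoys = 25L,
      decoyLenRange = c(60L, 200L), seed = 7L)
  .testCache$fx
}

miniSurvey <- function() {
  if (is.null(.testCache$survey)) {
    fx <- miniFixture()
    .testCache$survey <- runSurveyCore(
      fx$taxonomy, fx$proteomes, fx$families, fx$seedAlignments,
      fx$domainAlignments, fx$refOrganism, nNull = 300L, seed = 3L)
  }
  .testCache$survey
}

# a toy two-chain PDB text: each residue described as (chain, resno, resname,
# list of atoms with name and coordinates)
pdbText <- function(residues) {
  lines <- character()
  serial <- 0L
  for (r in residues) {
    for (a in r$atoms) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, substr(a$name, 1, 4), " ", r$resname, r$chain, r$resno, " ",
        a$x, a$y, a$z, 1.0, 10.0,
        if (is.null(a$elem)) substr(a$name, 1, 1) else a$elem))
    }
  }
  c(lines, "END")
}

writeTempLines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
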