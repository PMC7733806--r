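# fixture builders shared across the suite; everything is generated in
# code, nothing is read from disk except files the helpers write to
# tempdir()

pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     occ = 1, altloc = " ", element = NULL, het = FALSE) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          altloc, resname, chain, resseq, x, y, z, occ, 0, element)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a tiny structure from an inline coordinate spec:
# list(c(name, resname, resseq, x, y, z), ...)
mini_structure <- function(spec, chain = "A", source_id = "mini") {
  rows <- lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    data.frame(serial = i, name = s[[1]], altloc = "", resname = s[[2]],
               chain = chain, resseq = as.integer(s[[3]]), icode = "",
               x = as.numeric(s[[4]]), y = as.numeric(s[[5]]),
               z = as.numeric(s[[6]]), occupancy = 1,
               element = substr(gsub("[0-9]", "", s[[1]]), 1, 1),
               het = FALSE, stringsAsFactors = FALSE)
  })
  new_structure(do.call(rbind, rows), source_id = source_id)
}

# poly-ALA CA chain of n residues: a shallow zig-zag (not collinear, so
# the chain can be superposed)
poly_ala <- function(n, spacing = 3.8) {
  mini_structure(lapply(seq_len(n), function(i)
    list("CA", "ALA", i, spacing * i, i %% 2, (i %% 3) / 2)),
    source_id = "polyA")
}

random_rotation <- function() {
  rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
}

# shared expensive fixture: built once per test run
pump_pair_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_pump_pair(seed = 1)
    cache
  }
})
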