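## State alphabets and character-level encoding.
##
## Two alphabets are supported: "nt" (A C G T) and "aa" (20 amino acids in
## PAML order).  Gaps ('-', '.'), unknowns ('N' for nt, 'X' for aa) and any
## IUPAC ambiguity code are all treated as fully missing: in the likelihood
## they contribute a partial vector of ones (no partial resolution of
## ambiguity codes).

.NT_STATES <- c("A", "C", "G", "T")

.alphabetStates <- function(alphabet) {
  switch(match.arg(alphabet, c("nt", "aa")),
         nt = .NT_STATES,
         aa = .WAG_STATES)
}

.NT_AMBIG <- c("N", "U", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
               "-", ".", "?", "O")
.AA_AMBIG <- c("X", "B", "Z", "J", "U", "O", "-", ".", "?", "*")

# Validate characters; returns invisible TRUE or stops.
.checkAlphabet <- function(chars, alphabet) {
  states <- .alphabetStates(alphabet)
  extra <- if (alphabet == "nt") .NT_AMBIG else .AA_AMBIG
  bad <- setdiff(unique(toupper(chars)), c(states, extra))
  if (length(bad))
    stop("illegal character(s) for alphabet '", alphabet, "': ",
         paste(bad, collapse = " "), call. = FALSE)
  invisible(TRUE)
}

# Integer codes 1..k for observed states, NA for gap/ambiguity/missing.
.encodeChars <- function(chars, alphabet) {
  states <- .alphabetStates(alphabet)
  .checkAlphabet(chars, alphabet)
  match(toupper(chars), states)
}

.isMissingChar <- function(chars, alphabet) {
  is.na(match(toupper(chars), .alphabetStates(alphabet)))
}
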