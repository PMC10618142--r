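.onLoad <- function(libname, pkgname) {
  # frozen structural contracts of the feature spaces
  stopifnot(length(ASHN_POS_TAGS) == 48L,
            !anyDuplicated(ASHN_POS_TAGS),
            length(ASHN_SENTIMENTS) == 3L)
  validate_symptom_lexicon(builtin_symptom_lexicon())
  invisible(NULL)
}
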