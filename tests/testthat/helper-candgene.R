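# Add the derived analysis columns the regression stages expect.
prep_subjects <- function(s) {
  s$status_bin <- as.integer(s$status == "case")
  s$sex_male <- as.integer(s$sex == "M")
  s$log_homa <- log(s$homa_ir)
  s$log_tg <- log(s$tg)
  s
}

# Annotation vector matching the headline composition of the
# resequencing screen: 100 intronic, 68 exonic of which 43 missense,
# 2 nonsense, 2 frameshift, 21 synonymous.
screen_annotation <- function() {
  c(rep("intronic", 100), rep("missense", 43), rep("nonsense", 2),
    rep("frameshift", 2), rep("synonymous", 21))
}
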