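# HGVS p. strings for the characterized and newly reported Maturity/Dwarf
# variants; the parser must accept each and re-format it identically.
CHARACTERIZED_HGVS <- c(
  "p.(Gln270Ter)", "p.(Lys184Asn)", "p.(Gln292Ter)", "p.(Ile126Lys)",
  "p.(Gly177ArgfsTer4)", "p.(Ser443Ter)", "p.(Gln494Ter)", "p.(Cys90Ter)",
  "p.(Val95GlnfsTer16)", "p.(Gly209GlufsTer74)", "p.(Val106Asp)",
  "p.(Met160Leu)", "p.(Asn117Thr)", "p.(Arg187Cys)", "p.(Ser210Cys)",
  "p.(Asp236Tyr)", "p.(Trp264Arg)",
  "p.(Leu141Ter)", "p.(Met83Thr)", "p.(Gly23Ala)", "p.(Leu112Ile)",
  "p.(Tyr196Phe)", "p.(Arg338Trp)",
  "p.(Asn1023MetfsTer11)", "p.(His31dup)", "p.(His31del)",
  "p.(Asp308Gly)", "p.(Leu1113Val)", "p.(Asp636Tyr)", "p.(Pro346Leu)",
  "p.(Arg337Gln)", "p.(Lys214Asn)", "p.(Leu132Phe)",
  "p.(Glu295AlafsTer16)", "p.(Glu295AlafsTer19)", "p.(Glu295GlyfsTer25)",
  "p.(Gly124Val)", "p.(Gly162Arg)", "p.(Val190Ala)", "p.(Glu922Asp)",
  "p.(Gly981Asp)", "p.(Thr653Ser)", "p.(Met437Thr)", "p.(Thr371Ile)",
  "p.(Gln274Glu)", "p.(Ser49Tyr)",
  "p.(Glu94AspfsTer6)", "p.(Glu94SerfsTer77)", "p.(Cys6Tyr)",
  "p.(Arg220Gln)", "p.(Cys14ThrfsTer154)", "p.(Arg220GlyfsTer2)",
  "p.(Gln76Ter)",
  "p.(Lys199Ter)", "p.(Gln398His)",
  "p.(Leu184IlefsTer8)", "p.(Glu183AspfsTer27)", "p.(Ser160Cys)",
  "p.(Leu1435GlyfsTer120)", "p.(Gln1174_Arg1175del)",
  "p.(Arg311GlnfsTer37)", "p.(Cys17TrpfsTer123)", "p.(Cys17AspfsTer54)",
  "p.(Met599AsnfsTer956)", "p.(Gly307AlafsTer18)", "p.(Gly887Arg)",
  "p.(Arg403Pro)", "p.(Glu64Val)", "p.(Gln475Ter)", "p.(Glu322Ter)")

random_protein_change <- function() {
  aas <- setdiff(unname(sorgscreen:::AA_1TO3), c("Ter", "Xaa"))
  kind <- sample(c("missense", "nonsense", "frameshift", "inframe_del",
                   "inframe_dup", "inframe_ins", "inframe_delins",
                   "synonymous", "start_loss", "stop_loss"), 1)
  pos <- sample(1:2000, 1)
  switch(kind,
    synonymous = protein_change("synonymous"),
    start_loss = protein_change("start_loss", pos = 1, ref_aa = "Met"),
    missense = protein_change("missense", pos = pos,
                              ref_aa = sample(aas, 1),
                              alt_aa = sample(aas, 1)),
    nonsense = protein_change("nonsense", pos = pos,
                              ref_aa = sample(aas, 1), alt_aa = "Ter"),
    stop_loss = protein_change("stop_loss", pos = pos, ref_aa = "Ter",
                               alt_aa = sample(aas, 1)),
    frameshift = {
      ns <- runif(1) < 0.1
      protein_change("frameshift", pos = pos, ref_aa = sample(aas, 1),
                     alt_aa = sample(aas, 1),
                     ter_offset = if (ns) NA else sample(1:999, 1),
                     no_stop = ns)
    },
    inframe_del = {
      k <- sample(1:3, 1)
      protein_change("inframe_del", pos = pos, ref_aa = sample(aas, 1),
                     pos2 = if (k > 1) pos + k - 1 else NA,
                     ref_aa2 = if (k > 1) sample(aas, 1) else NA)
    },
    inframe_dup = {
      k <- sample(1:3, 1)
      protein_change("inframe_dup", pos = pos, ref_aa = sample(aas, 1),
                     pos2 = if (k > 1) pos + k - 1 else NA,
                     ref_aa2 = if (k > 1) sample(aas, 1) else NA)
    },
    inframe_ins = protein_change("inframe_ins", pos = pos,
                                 ref_aa = sample(aas, 1), pos2 = pos + 1,
                                 ref_aa2 = sample(aas, 1),
                                 alt_aa = paste(sample(aas, sample(1:3, 1),
                                                       replace = TRUE),
                                                collapse = "")),
    inframe_delins = protein_change("inframe_delins", pos = pos,
                                    ref_aa = sample(aas, 1),
                                    pos2 = pos + sample(1:3, 1),
                                    ref_aa2 = sample(aas, 1),
                                    alt_aa = paste(sample(aas,
                                                          sample(1:3, 1),
                                                          replace = TRUE),
                                                   collapse = "")))
}
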