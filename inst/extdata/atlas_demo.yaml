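# Demonstration atlas configuration (SYNTHETIC geometry).
#
# The wing-disc systems (Wg, Hh, Dpp) have well-measured decay lengths but
# their patterned lengths and cell sizes are not part of the package's
# built-in registry; this file supplies plausible demonstration values so the
# full scoring pipeline can run end to end. These geometric entries are
# synthetic placeholders for demonstration and testing, NOT literature
# measurements -- replace them with your own curated values for real use.
morphogens:
  Wg:
    L_um: 35
    lcell_um: 2.6
    xb_rel_lo: 0.35
    xb_rel_hi: 0.45
    provenance:
      L_um: "user-demo (synthetic)"
      lcell_um: "user-demo (synthetic)"
      xb_rel_lo: "user-demo (synthetic)"
      xb_rel_hi: "user-demo (synthetic)"
  Hh:
    L_um: 45
    lcell_um: 2.6
    xb_rel_lo: 0.35
    xb_rel_hi: 0.45
    provenance:
      L_um: "user-demo (synthetic)"
      lcell_um: "user-demo (synthetic)"
      xb_rel_lo: "user-demo (synthetic)"
      xb_rel_hi: "user-demo (synthetic)"
  Dpp:
    L_um: 100
    lcell_um: 2.6
    provenance:
      L_um: "user-demo (synthetic)"
      lcell_um: "user-demo (synthetic)"
  Bcd:
    lcell_um: 10
    provenance:
      lcell_um: "derived from printed L/lcell = 50 with L = 500 um"
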