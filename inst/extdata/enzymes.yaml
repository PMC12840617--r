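# Protease cleavage-rule registry.
#
# Each entry maps an enzyme name to its site specificity:
#   c_terminal_of:   residues after which the bond is cut (P1)
#   n_terminal_of:   residues before which the bond is cut (P1')
#   blocked_p1prime: residues that veto the cut when immediately following
#                    the site (optional)
# Residue letters are quoted: unquoted Y/N/F parse as YAML booleans.
# Further enzymes (e.g. a full theoretical-digestion panel) can be added
# here without code changes and loaded with read_enzyme_rules().
pepsin:
  c_terminal_of: ["F", "I", "Y", "W"]
  n_terminal_of: ["M", "E", "L", "F"]
trypsin:
  c_terminal_of: ["H", "K", "R"]
chymotrypsin:
  c_terminal_of: ["F", "Y", "W"]
bromelain:
  # cuts between hydrophobic and basic residues: hydrophobic P1 with the
  # non-basic P1' residues vetoed
  c_terminal_of: ["A", "V", "L", "I", "P", "F", "M", "W", "G"]
  blocked_p1prime: ["A", "C", "D", "E", "F", "G", "I", "L", "M", "N", "P",
                    "Q", "S", "T", "V", "W", "Y"]
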