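{
  "comment": "Registered nomenclature tokens. Prefix tokens must be followed by a locant list (digits, comma-separated). Cores terminate a name; the 'ops' list gives operations implied by the core itself; atomic cores name multi-step family symbols whose internal chemistry is not decomposed.",
  "prefixes": {
    "m": {"kind": "methylation"},
    "s": {"kind": "thiolation"},
    "se": {"kind": "selenation"},
    "ges": {"kind": "geranylthiolation"},
    "ac": {"kind": "acetylation"},
    "acp": {"kind": "aminocarboxypropylation"},
    "f": {"kind": "formylation"},
    "g": {"kind": "glycinylcarbamoylation"},
    "hm": {"kind": "hydroxymethylation"},
    "ho": {"kind": "hydroxylation"},
    "hn": {"kind": "complex", "notes": "hydroxynorvalylcarbamoyl group"},
    "ht": {"kind": "threonylcarbamoylation", "notes": "hydroxylated threonylcarbamoyl group, one registered token"},
    "i": {"kind": "isopentenylation"},
    "io": {"kind": "isopentenylation", "notes": "cis-hydroxyisopentenyl group, one registered token"},
    "inm": {"kind": "aminomethyl-side-chain", "notes": "isopentenylaminomethyl variant"},
    "mo": {"kind": "methoxylation"},
    "cm": {"kind": "carboxymethyl-side-chain"},
    "chm": {"kind": "carboxymethyl-side-chain", "notes": "carboxyhydroxymethyl variant, one registered token"},
    "cmo": {"kind": "carboxymethyl-side-chain", "notes": "oxyacetic acid variant"},
    "mcm": {"kind": "carboxymethyl-side-chain", "notes": "methoxycarbonylmethyl variant"},
    "mchm": {"kind": "carboxymethyl-side-chain", "notes": "carboxyhydroxymethyl methyl ester, registered as one token"},
    "mcmo": {"kind": "carboxymethyl-side-chain", "notes": "oxyacetic acid methyl ester variant"},
    "ncm": {"kind": "carbamoylmethyl-side-chain"},
    "nchm": {"kind": "carbamoylmethyl-side-chain", "notes": "carbamoylhydroxymethyl variant"},
    "cnm": {"kind": "complex", "notes": "cyanomethyl group; census extension beyond the base vocabulary"},
    "cmnm": {"kind": "aminomethyl-side-chain", "notes": "carboxymethylaminomethyl variant"},
    "mnm": {"kind": "aminomethyl-side-chain", "notes": "methylaminomethyl variant"},
    "nm": {"kind": "aminomethyl-side-chain"},
    "tm": {"kind": "taurinomethyl-side-chain"},
    "t": {"kind": "threonylcarbamoylation"},
    "ct": {"kind": "threonylcarbamoylation", "notes": "cyclic form, one registered token"},
    "ms": {"kind": "thiolation", "notes": "methylthio, one operation"},
    "msms": {"kind": "thiolation", "notes": "methylthiomethylenethio, one operation"},
    "k": {"kind": "lysidination"}
  },
  "suffixes": {
    "m": {"kind": "2'-O-methylation", "site": "2'-O"},
    "r(p)": {"kind": "2'-O-ribosylation", "site": "2'-O"}
  },
  "cores": {
    "A": {"root": "A", "ops": [], "atomic": false},
    "C": {"root": "C", "ops": [], "atomic": false},
    "G": {"root": "G", "ops": [], "atomic": false},
    "U": {"root": "U", "ops": [], "atomic": false},
    "I": {"root": "A", "ops": ["deamination"], "atomic": false},
    "Ψ": {"root": "U", "ops": ["isomerization"], "atomic": false},
    "D": {"root": "U", "ops": ["reduction"], "atomic": false},
    "C+": {"root": "C", "ops": ["agmatination"], "atomic": false},
    "Q": {"root": "G", "ops": [], "atomic": true},
    "G+": {"root": "G", "ops": [], "atomic": true},
    "preQ0": {"root": "G", "ops": [], "atomic": true},
    "preQ1": {"root": "G", "ops": [], "atomic": true},
    "oQ": {"root": "G", "ops": [], "atomic": true},
    "galQ": {"root": "G", "ops": [], "atomic": true},
    "manQ": {"root": "G", "ops": [], "atomic": true},
    "gluQ": {"root": "G", "ops": [], "atomic": true},
    "imG-14": {"root": "G", "ops": [], "atomic": true},
    "imG": {"root": "G", "ops": [], "atomic": true},
    "imG2": {"root": "G", "ops": [], "atomic": true},
    "mimG": {"root": "G", "ops": [], "atomic": true},
    "yW": {"root": "G", "ops": [], "atomic": true},
    "yW-58": {"root": "G", "ops": [], "atomic": true},
    "yW-72": {"root": "G", "ops": [], "atomic": true},
    "yW-86": {"root": "G", "ops": [], "atomic": true},
    "o2yW": {"root": "G", "ops": [], "atomic": true},
    "OHyW": {"root": "G", "ops": [], "atomic": true},
    "OHyWx": {"root": "G", "ops": [], "atomic": true},
    "OHyWy": {"root": "G", "ops": [], "atomic": true}
  },
  "aliases": {
    "psi": "Ψ",
    "psi-m": "Ψm",
    "m1psi": "m1Ψ",
    "m3psi": "m3Ψ",
    "acp3psi": "acp3Ψ",
    "m1acp3psi": "m1acp3Ψ"
  }
}
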