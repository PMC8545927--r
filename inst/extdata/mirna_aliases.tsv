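# Editable alias table applied during miRNA name canonicalization.
# `from` is matched as a family prefix on the canonical (lower-case,
# hsa-stripped) form; arm suffixes are preserved.  Only corrections of
# evident typographical errors belong here by default.
from	to
leg-7g	let-7g
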