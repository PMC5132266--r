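>TM4_fragment_synthetic offset=261 synthetic stand-in carrying the anchor residues V265/Y267/F268/K272 at their native numbering
AGTSVAYFGASKTGA
>TM10_fragment_synthetic offset=486 synthetic stand-in carrying the anchor residues K490/Y495/V501 at their native numbering
AGSTKAGSTYAGSTAVGATS
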