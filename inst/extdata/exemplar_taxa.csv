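taxon,clade,fusion_any,fusion_type
Amborella,amborellales,no,none
Trithuria,hydatellaceae,unknown,unknown
Cabomba,cabombaceae,no,none
Brasenia,cabombaceae,no,none
Nuphar,rogue_nuphar,yes,congenital
Nymphaea,nymphaeoideae,yes,congenital
Victoria,nymphaeoideae,yes,congenital
Austrobaileya,austrobaileyales,no,none
Schisandra,austrobaileyales,no,none
Hedyosmum,chloranthaceae,inapplicable,unknown
Ascarina,chloranthaceae,inapplicable,unknown
Sarcandra,chloranthaceae,inapplicable,unknown
Chloranthus,chloranthaceae,inapplicable,unknown
Magnolia,magnoliids,no,none
Liriodendron,magnoliids,no,none
Laurus,magnoliids,inapplicable,unknown
Annona,magnoliids,yes,postgenital
Piper,magnoliids,yes,congenital
Asarum,magnoliids,yes,congenital
Acorus,monocots_other,yes,congenital
Arum,monocots_araceae,yes,congenital
Spathiphyllum,monocots_araceae,yes,congenital
Tofieldia,rogue_tofieldiaceae,no,none
Alisma,monocots_other_alismatales,no,none
Butomus,monocots_other_alismatales,no,none
Lilium,monocots_other,yes,congenital
Oryza,monocots_other,yes,congenital
Euptelea,rogue_euptelea,no,none
Papaver,eudicots_papaveraceae,yes,congenital
Ranunculus,eudicots_other_ranunculales,no,none
Berberis,eudicots_other_ranunculales,inapplicable,unknown
Platanus,eudicots_other,no,none
Arabidopsis,eudicots_other,yes,congenital
Vitis,eudicots_other,yes,congenital
Citrus,eudicots_other,yes,both
Asclepias,eudicots_other,yes,postgenital
Helianthus,eudicots_other,yes,congenital
Ceratophyllum,rogue_ceratophyllum,unknown,unknown
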