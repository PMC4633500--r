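>pda-miR156a
UGACAGAAGAGAGUGAGCAC
>pda-miR156h
UUGACAGAAGAUAGAGAGCAC
>pda-miR160a-5p
UGCCUGGCUCCCUGUAUGCCA
>pda-miR166a
UCGGACCAGGCUUCAUUCCCC
>pda-miR166i-3p
UCUCGGAUCAGGCUUCAUUCC
>pda-miR167a
UGAAGCUGCCAGCAUGAUCUA
>pda-miR168a
UCGCUUGGUGCAGGUCGGGA
>pda-miR169a
UAGCCAAGGAUGACUUGCCU
>pda-miR172b-5p
UGGCAUCAUCAAGAUUCACAU
>pda-miR390a
AAGCUCAGGAGGGAUAGCGCC
>pda-miR393a
UCCAAAGGGAUCGCAUUGAUC
>pda-miR394a-5p
UUGGCAUUCUGUCCACCUCC
>pda-miR395
CUGAAGUGUUUGGGGGAACG
>pda-miR396a-5p
UCACAGGCUUUCUUGAACU
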