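>synthetic_consensus_KS
DHPTTVTVLKFHLTDSGRGQHTRSMLPTALVWNMESIFPESVGVAQHHFDTQVLEGAKSSGEGDNYHSCVVASRSLLWDV
DAASTPEPVTTTAYGTGGCSVGSKPKVGLTDTGLKYGDPFRDVADKGTGRTFLSGIVRIVVLVVCPPSGCMRSGAPKPGH
DADAMEKLYAVVTVGQAPDQLGLADTRPCGGTPAKTNPYEFPVGAQRIFKAFVRVAARAGGASHPMGTSILLLQPPNSNG
ESGPECIAEFTGYLVIDAPTEQTHPWVQLFPDYFGANQQIGKGKLFAARTVEPGFKCTAVWDKMHQSAVGTDGEIEGSCD
VNVIGYVGEPVDGGASLIELFISCGTADAWGPPAVKIENIAYSAKLLGKARVYSELRAQDGVNVRVRQVESEASMLEVDM
QALNIPFPDIKDADFQHVSPSTSFCDSDAK
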