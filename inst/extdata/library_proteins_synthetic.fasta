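>Thyroglobulin synthetic stand-in assembled from documented tryptic reference peptides
QQAAALAKFPLGESFLAAKKGQEFTITGQKRKFEKLPESKSLSLKLTDEELAFPPLSPSR
FAATSFRKVVLQDRAFLGTVRAVKQFEESQGRAISVPEDIARASGLGAAAGQRGQEIPGT
RELSVLLPNRGSGSAGSGA
>BSA synthetic stand-in assembled from documented tryptic reference peptides
ADLAKLVNELTEFAKLVTDLTKKQTALVELLKAEFVEVTKKVPQVSTPTLVEVSRIETMR
GSAGSSGA
>alpha-Hemoglobin synthetic stand-in modeled on the mature human alpha chain
VLSPADKTNVKAAWGKVGAHAGEYGAEALERMFLSFPTTKTYFPHFDLSHGSAQVKGHGK
KVADALTNAVAHVDDMPNALSALSDLHAHKLRVDPVNFKLLSHCLLVTLAAHLPAEFTPA
VHASLDKFLASVSTVLTSKYR
>beta-Hemoglobin synthetic stand-in modeled on the mature human beta chain
VHLTPEEKSAVTALWGKVNVDEVGGEALGRLLVVYPWTQRFFESFGDLSTPDAVMGNPKV
KAHGKKVLGAFSDGLAHLDNLKGTFATLSELHCDKLHVDPENFRLLGNVLVCVLAHHFGK
EFTPPVQAAYQKVVAGVANALAHKYH
>alpha-Lactalbumin synthetic stand-in with a cysteine/tyrosine-rich composition
EQLTKCEVFRELKDLKGYGGVSLPEWVCTTFHTSGYDTQAIVQNNDSTEYGLFQINNKIW
CKDDQNPHSSNICNISCDKFLDDDLTDDIMCVKKILDKVGINYWLAHKALCSEKLDQWLC
EKL
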