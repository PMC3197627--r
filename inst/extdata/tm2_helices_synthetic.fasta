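>TarEc_WT|Tar_Ecoli|WY_scan|wildtype|188
AFLVWLAIVLAILVFAILIALWYIRKLALS
>WYm3|Tar_Ecoli|WY_scan|kinase_inactive|188
AFLVWLAIVLAILVFAILWYIALIRKLALS
>WYm2|Tar_Ecoli|WY_scan|kinase_inactive|188
AFLVWLAIVLAILVFAILIWYALIRKLALS
>WYm1|Tar_Ecoli|WY_scan|kinase_inactive|188
AFLVWLAIVLAILVFAILIAWYLIRKLALS
>WYp1|Tar_Ecoli|WY_scan|kinase_active|188
AFLVWLAIVLAILVFAILIALIWYRKLALS
>WYp2|Tar_Ecoli|WY_scan|kinase_active|188
AFLVWLAIVLAILVFAILIALIRWYKLALS
>WYp3|Tar_Ecoli|WY_scan|kinase_active|188
AFLVWLAIVLAILVFAILIALIRKWYLALS
>W192A|Tar_Ecoli|WA_point|mixed|188
AFLVALAIVLAILVFAILIALWYIRKLALS
>W209A|Tar_Ecoli|WA_point|kinase_inactive|188
AFLVWLAIVLAILVFAILIALAYIRKLALS
>W192A_W209A|Tar_Ecoli|WA_point|kinase_inactive|188
AFLVALAIVLAILVFAILIALAYIRKLALS
>TarSt_WT|Tar_Styphimurium|Arg_scan_Tar|wildtype|188
AFLVWLAVVLAILVFAVLIALWYIRKLALS
>F189R|Tar_Styphimurium|Arg_scan_Tar|kinase_active|188
ARLVWLAVVLAILVFAVLIALWYIRKLALS
>W192R|Tar_Styphimurium|Arg_scan_Tar|kinase_active|188
AFLVRLAVVLAILVFAVLIALWYIRKLALS
>W209R|Tar_Styphimurium|Arg_scan_Tar|kinase_inactive|188
AFLVWLAVVLAILVFAVLIALRYIRKLALS
>TrgEc_WT|Trg_Ecoli|Basic_Trg|wildtype|201
SKLAFLAVIALVVITLLIALFAIWYLRKLS
>T215K|Trg_Ecoli|Basic_Trg|kinase_active|201
SKLAFLAVIALVVIKLLIALFAIWYLRKLS
>T215R|Trg_Ecoli|Basic_Trg|kinase_active|201
SKLAFLAVIALVVIRLLIALFAIWYLRKLS
>L216R|Trg_Ecoli|Basic_Trg|kinase_inactive|201
SKLAFLAVIALVVITRLIALFAIWYLRKLS
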