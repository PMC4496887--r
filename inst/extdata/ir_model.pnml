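<?xml version="1.0" encoding="UTF-8"?>
<pnml xmlns="http://www.pnml.org/version-2009/grammar/pnml">
  <net id="net1" type="http://www.pnml.org/version-2009/grammar/ptnet">
    <page id="page1">
      <place id="Insulin">
        <name>
          <text>Insulin</text>
        </name>
        <initialMarking>
          <text>0</text>
        </initialMarking>
        <toolspecific tool="stochpn" version="1">
          <constant>true</constant>
          <expression>Time % 86400 &gt;= 32400 , Time % 86400 &lt; 43200 : 36000 + 180000 * exp(-(Time % 86400 - 32400) / 2345.19020227756) ; Time % 86400 &gt;= 46800 , Time % 86400 &lt; 57600 : 36000 + 180000 * exp(-(Time % 86400 - 46800) / 2345.19020227756) ; Time % 86400 &gt;= 64800 , Time % 86400 &lt; 75600 : 36000 + 180000 * exp(-(Time % 86400 - 64800) / 2345.19020227756) ; 36000</expression>
        </toolspecific>
      </place>
      <place id="IR">
        <name>
          <text>IR</text>
        </name>
        <initialMarking>
          <text>540</text>
        </initialMarking>
      </place>
      <place id="IR_I">
        <name>
          <text>IR_I</text>
        </name>
        <initialMarking>
          <text>0</text>
        </initialMarking>
      </place>
      <place id="IR_I_P">
        <name>
          <text>IR_I_P</text>
        </name>
        <initialMarking>
          <text>0</text>
        </initialMarking>
      </place>
      <place id="IR_I_P_Int">
        <name>
          <text>IR_I_P_Int</text>
        </name>
        <initialMarking>
          <text>0</text>
        </initialMarking>
      </place>
      <place id="IR_Int">
        <name>
          <text>IR_Int</text>
        </name>
        <initialMarking>
          <text>60</text>
        </initialMarking>
      </place>
      <transition id="Bind_Insulin">
        <name>
          <text>Bind_Insulin</text>
        </name>
      </transition>
      <transition id="Diss_Insulin">
        <name>
          <text>Diss_Insulin</text>
        </name>
      </transition>
      <transition id="Inter_IR">
        <name>
          <text>Inter_IR</text>
        </name>
      </transition>
      <transition id="Phos_IR_I">
        <name>
          <text>Phos_IR_I</text>
        </name>
      </transition>
      <transition id="Dephos_IR_I_P">
        <name>
          <text>Dephos_IR_I_P</text>
        </name>
      </transition>
      <transition id="Inter_IR_I_P">
        <name>
          <text>Inter_IR_I_P</text>
        </name>
      </transition>
      <transition id="Deinter_IR_I_P">
        <name>
          <text>Deinter_IR_I_P</text>
        </name>
      </transition>
      <transition id="Dephos_IR_I_P_Int">
        <name>
          <text>Dephos_IR_I_P_Int</text>
        </name>
      </transition>
      <transition id="Deinter_IR">
        <name>
          <text>Deinter_IR</text>
        </name>
      </transition>
      <transition id="Degradation">
        <name>
          <text>Degradation</text>
        </name>
      </transition>
      <transition id="Synthesis">
        <name>
          <text>Synthesis</text>
        </name>
      </transition>
      <arc id="a1" source="Insulin" target="Bind_Insulin"/>
      <arc id="a2" source="IR" target="Bind_Insulin"/>
      <arc id="a3" source="Bind_Insulin" target="IR_I"/>
      <arc id="a4" source="IR_I" target="Diss_Insulin"/>
      <arc id="a5" source="Diss_Insulin" target="IR"/>
      <arc id="a6" source="IR" target="Inter_IR"/>
      <arc id="a7" source="Inter_IR" target="IR_Int"/>
      <arc id="a8" source="IR_I" target="Phos_IR_I"/>
      <arc id="a9" source="Phos_IR_I" target="IR_I_P"/>
      <arc id="a10" source="IR_I_P" target="Dephos_IR_I_P"/>
      <arc id="a11" source="Dephos_IR_I_P" target="IR_I"/>
      <arc id="a12" source="IR_I_P" target="Inter_IR_I_P"/>
      <arc id="a13" source="Inter_IR_I_P" target="IR_I_P_Int"/>
      <arc id="a14" source="IR_I_P_Int" target="Deinter_IR_I_P"/>
      <arc id="a15" source="Deinter_IR_I_P" target="IR_I_P"/>
      <arc id="a16" source="IR_I_P_Int" target="Dephos_IR_I_P_Int"/>
      <arc id="a17" source="Dephos_IR_I_P_Int" target="IR_Int"/>
      <arc id="a18" source="IR_Int" target="Deinter_IR"/>
      <arc id="a19" source="Deinter_IR" target="IR"/>
      <arc id="a20" source="IR_Int" target="Degradation"/>
      <arc id="a21" source="Synthesis" target="IR_Int"/>
    </page>
  </net>
</pnml>
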